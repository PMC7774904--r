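# Variant D with Tgfb loss of function (Smad3 block, beta = 0): no self-organisation; the Shh gradient alone polarises Pax6.
variant: D
lof: tgfb_lof
geometry:
  type: explant
  long_axis: 16.0
  short_axis: 8.0
  dx: 0.5
  shape: capsule
ic:
  type: noisy_homogeneous
  noise_amplitude: 0.05
shh:
  peak: 0.5
  form: linear
  axis: long
  inverted: false
seed: 1
t_end: 10000.0
snapshot_interval: 83.0
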