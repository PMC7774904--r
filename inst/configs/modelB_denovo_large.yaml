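# Variant B on a two-wavelength ring: multiple Pax6 poles.
variant: B
geometry:
  type: grid1d
  n_points: 305
  dx: 0.25
  boundary: periodic
ic:
  type: noisy_homogeneous
  noise_amplitude: 0.05
seed: 1
t_end: 10000.0
snapshot_interval: 83.0
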