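# Variant B kinetics on a 2:1 capsule explant with an initial
# distal-high Pax6 gradient across the SHORT axis: the pattern
# re-polarises along the long axis.
variant: C
geometry:
  type: explant
  long_axis: 16.0
  short_axis: 8.0
  dx: 0.5
  shape: capsule
ic:
  type: distal_high_prepattern
  high_value: 12.3
  low_value: 11.2
  axis: short
  profile: linear
seed: 1
t_end: 10000.0
snapshot_interval: 83.0
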