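# Variant A: Pax6 frozen as a regional (distal-high) step pattern on a
# 1D anterior-posterior axis; Fst/Tgfb2/complex/receptor fields respond.
variant: A
geometry:
  type: grid1d
  n_points: 79
  dx: 1.0
  boundary: zero_flux
ic:
  type: fixed_pax6_source
  high_value: 11.7
  low_value: 0.3
  profile: step
seed: 1
t_end: 5000.0
snapshot_interval: 50.0
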