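# Example simulation configuration: a coarse study heart with the full
# default pacing sweep.
mesh:
  n_circumferential: 24
  n_transmural: 2
  n_transmural_rv: 1
fibers:
  endo_angle_deg: 60
  epi_angle_deg: -60
conduction:
  fast_shell_multiplier: 6
  lbbb: true
electrics:
  dt: 0.1
  t_end: 250
  threshold: 0.5
mechanics:
  tmax_kpa: 10
  t_rise_ms: 60
  t_decay_ms: 80
  base_spring: 50
sweep:
  lv_sites: [POST-B, POST-E, LAT-B, LAT-E, ANT-B, ANT-E]
  vvd_values: [-72, -60, -48, -36, -24, -12, 0, 12, 24, 36, 48, 60, 72]
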