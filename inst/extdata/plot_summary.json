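{
  "total_stems_geq_1cm": 95498,
  "window_m": [500, 400],
  "elevation_range_m": [709, 869],
  "quadrat_size_m": 20
}
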