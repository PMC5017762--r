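{
  "beta_sbp": 0.015,
  "beta_tc": 0.25,
  "beta_ratio": 0.35,
  "beta_smoke": 0.7,
  "provenance": "synthetic illustrative values for examples and demos; not estimates from any cohort analysis"
}
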