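{
  "threshold": {"k": 20000, "currency": "EUR"},
  "population": 10000,
  "static": {
    "baseline_levels": [0.20, 0.40],
    "strategy_levels": [0.40, 0.60]
  },
  "dynamic": {
    "horizon": 15,
    "diffusion_start": 0.09,
    "diffusion_step": 0.06,
    "strategy_offset": 0.03,
    "rate": 0.03,
    "current_value_convention": "first_year_discounted",
    "strategy_value_convention": "first_year_undiscounted"
  }
}
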