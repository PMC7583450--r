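# MammaPrint dynamic current-value scenario: varying NMB from the
# OLS meta-model fitted to the packaged decision-model triples.
# Year 1 is discounted under this stream's convention.
threshold:
  k: 20000
  currency: EUR
profile:
  kind: fit
  path: mammaprint_marginals.csv
  rounded: true
dynamic:
  horizon: 15
  population: 10000
  diffusion:
    start: 0.09
    step: 0.06
  strategy_offset: 0.03
  rate: 0.03
  convention: first_year_discounted
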