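# Static value-of-implementation scenario: constant per-patient NMB.
threshold:
  k: 20000
  currency: EUR
profile:
  kind: constant
  delta_qaly: 0.1492
  delta_cost: 1171
# "n" is quoted: a bare n is YAML-1.1 shorthand for a boolean
static:
  "n": 10000
  p: 0.20
  sigma: 0.40
  strategy_cost: 1000000
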