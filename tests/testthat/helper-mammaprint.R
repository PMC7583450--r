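# Published MammaPrint case-study values frozen for comparison.

mp_triples <- data.frame(
  p = c(0.03, 0.50, 0.92),
  delta_qaly = c(0.001, 0.0728, 0.1492),
  delta_cost = c(1940, 1630, 1171))

mp_k <- 20000

# Current value of the diffusing uptake, 15 years, year 1 discounted.
mp_current_constant <- c(
  1584175, 2563390, 3484219, 4349233, 5160902, 5921600, 6633607, 7299115,
  7920227, 8498966, 9037273, 9537013, 9999975, 10427877, 10822370)
mp_current_varying <- c(
  -1519899, -2104440, -2377955, -2366098, -2093055, -1581619, -853258, 71824,
  1174623, 2437277, 3843010, 5376077, 7021714, 8766089, 10596252)
mp_current_totals <- c(constant = 103239942, varying = 26390541)

# Actual value of the +3-percentage-point strategy, year 1 undiscounted.
mp_strategy_constant <- c(
  543900, 528058, 512678, 497746, 483248, 469173, 455508, 442240, 429360,
  416854, 404713, 392925, 381481, 370369, 359582)
mp_strategy_varying <- c(
  -371208, -214159, -65944, 73819, 205496, 329441, 445991, 555472, 658197,
  754467, 844570, 928785, 1007378, 1080604, 1148711)
mp_strategy_totals <- c(constant = 6687834, varying = 7381619)
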