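# Independent oracles: plain-loop recomputations that avoid the
# package's vectorised stream code paths and lm-based fitting.

# Closed-form simple linear regression.
ols_line <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(slope = slope, intercept = yb - slope * xb)
}

ols_r2 <- function(x, y) {
  cf <- ols_line(x, y)
  res <- y - (cf[["slope"]] * x + cf[["intercept"]])
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# NMB evaluated straight from the profile's stored fields.
oracle_nmb <- function(profile, k, p) {
  eval_comp <- function(comp, p) {
    if (comp$kind == "constant") return(comp$value)
    if (comp$kind == "linear") return(comp$slope * p + comp$intercept)
    kp <- comp$p; kv <- comp$value
    i <- max(1L, min(length(kp) - 1L, findInterval(p, kp)))
    kv[i] + (kv[i + 1L] - kv[i]) / (kp[i + 1L] - kp[i]) * (p - kp[i])
  }
  k * eval_comp(profile$health, p) - eval_comp(profile$cost, p)
}

# Year-by-year loop totals for the four dynamic streams.
oracle_stream_total <- function(sched, profile, k, rate, convention,
                                kind = c("current", "perfect", "actual", "net")) {
  kind <- match.arg(kind)
  total <- 0
  for (t in seq_len(sched$horizon)) {
    n <- sched$population[t]
    p <- sched$baseline[t]
    yearly <- switch(kind,
      current = n * p * oracle_nmb(profile, k, p),
      perfect = n * (oracle_nmb(profile, k, 1) - p * oracle_nmb(profile, k, p)),
      actual = n * (sched$strategy[t] * oracle_nmb(profile, k, sched$strategy[t]) -
                      p * oracle_nmb(profile, k, p)),
      net = n * (sched$strategy[t] * oracle_nmb(profile, k, sched$strategy[t]) -
                   p * oracle_nmb(profile, k, p)) - sched$costs[t])
    expo <- if (convention == "first_year_undiscounted") t - 1 else t
    total <- total + yearly / (1 + rate)^expo
  }
  total
}
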