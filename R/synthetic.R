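# Seeded random scenarios for property-style testing.

#' Generate a random value-of-implementation scenario
#'
#' Draws a reproducible random scenario for property testing: a random
#' linear marginal profile (health slope in [-0.2, 0.2] QALY/patient
#' per unit uptake, health intercept in [0, 0.2]; cost slope in
#' [-2000, 2000] currency/patient per unit uptake, cost intercept in
#' [0, 3000]), a random linear diffusion path with a strategy offset,
#' a horizon of 5–20 years, a discount rate in [0, 0.06] and per-year
#' strategy costs. The same seed always yields the same scenario; the
#' caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @return a list of class `synthetic_scenario` with components
#'   `seed`, `profile`, `threshold`, `schedule` (a [schedule_set()])
#'   and `discount` (a [discount_spec()]).
#' @examples
#' sc <- random_scenario(42)
#' identical(sc, random_scenario(42))
#' @export
random_scenario <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  profile <- linear_profile(
    health_slope = stats::runif(1L, -0.2, 0.2),
    health_intercept = stats::runif(1L, 0, 0.2),
    cost_slope = stats::runif(1L, -2000, 2000),
    cost_intercept = stats::runif(1L, 0, 3000))
  horizon <- sample(5:20, 1L)
  start <- stats::runif(1L, 0, 0.5)
  step <- stats::runif(1L, 0, 0.1)
  offset <- stats::runif(1L, 0, 0.2)
  base <- linear_diffusion(start, step, horizon)
  schedule <- schedule_set(horizon,
                           population = sample(1000:50000, 1L),
                           baseline = base,
                           strategy = pmin(1, base + offset),
                           costs = stats::runif(horizon, 0, 1e5))
  structure(list(seed = as.integer(seed),
                 profile = profile,
                 threshold = threshold_policy(stats::runif(1L, 5000, 80000)),
                 schedule = schedule,
                 discount = discount_spec(stats::runif(1L, 0, 0.06))),
            class = "synthetic_scenario")
}
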