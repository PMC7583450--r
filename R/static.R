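# Single-period (static) value-of-implementation calculations.

#' Static value-of-implementation scenario
#'
#' Bundles the inputs of a single-period value-of-implementation
#' analysis: an eligible population of size `n`, a baseline
#' implementation level `p`, the level `sigma` reached after an
#' implementation strategy, the strategy's cost `strategy_cost`, and
#' the marginal profile and threshold that determine the per-patient
#' net monetary benefit.
#'
#' @param n eligible patients (count, >= 0).
#' @param p baseline implementation level in \eqn{[0, 1]}.
#' @param sigma post-strategy implementation level in \eqn{[0, 1]}.
#' @param profile a [marginal_profile][constant_profile].
#' @param threshold a [threshold_policy()].
#' @param strategy_cost one-off cost of the implementation strategy
#'   (currency, >= 0).
#' @return an object of class `static_scenario`.
#' @seealso [current_value()], [perfect_value()], [actual_value()],
#'   [net_value_of_strategy()]
#' @export
static_scenario <- function(n, p, sigma = p, profile, threshold, strategy_cost = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0,
            is.numeric(strategy_cost), length(strategy_cost) == 1L)
  if (strategy_cost < 0) stop("strategy_cost must be >= 0", call. = FALSE)
  check_level(p); check_level(sigma)
  stopifnot(length(p) == 1L, length(sigma) == 1L, is_marginal_profile(profile))
  structure(list(n = as.numeric(n), p = as.numeric(p), sigma = as.numeric(sigma),
                 profile = profile, threshold = as_threshold(threshold),
                 strategy_cost = as.numeric(strategy_cost)),
            class = "static_scenario")
}

#' @export
print.static_scenario <- function(x, ...) {
  cat(sprintf("Static VOI scenario: n = %g, p = %g -> sigma = %g, strategy cost = %g %s\n",
              x$n, x$p, x$sigma, x$strategy_cost, x$threshold$currency))
  invisible(x)
}

scenario_nmb <- function(s, p) net_monetary_benefit(s$profile, s$threshold, p)

#' Static value-of-implementation measures
#'
#' The population-level monetary value of an intervention's current,
#' perfect and strategy-achieved implementation in a single period,
#' with the per-patient net monetary benefit allowed to vary with the
#' implementation level:
#'
#' * `current_value()` — value at the level `level` (default the
#'   baseline `p`): \eqn{n \cdot p \cdot NMB(p)};
#' * `perfect_value()` — value forgone by not treating everyone:
#'   \eqn{n (NMB(1) - p\,NMB(p))};
#' * `actual_value()` — value of moving from `p` to `sigma`:
#'   \eqn{n (\sigma\,NMB(\sigma) - p\,NMB(p))}; equals `perfect_value()`
#'   at `sigma = 1`;
#' * `net_value_of_strategy()` — `actual_value()` minus the strategy
#'   cost.
#'
#' When the profile is constant these reduce to the familiar
#' constant-NMB forms \eqn{n\,p\,NMB}, \eqn{n(1-p)NMB},
#' \eqn{n(\sigma-p)NMB} and \eqn{n(\sigma-p)NMB - I}.
#'
#' @param s a [static_scenario()].
#' @param level implementation level at which to evaluate
#'   `current_value()`; defaults to the scenario baseline `p`.
#' @return a single currency value.
#' @examples
#' line_fit <- linear_profile(0.1662, -0.006, -860, 1996)
#' s <- static_scenario(10000, p = 0.2, sigma = 0.4,
#'                      profile = line_fit,
#'                      threshold = threshold_policy(20000))
#' current_value(s)   # -2558400
#' actual_value(s)    # 788800
#' @export
current_value <- function(s, level = s$p) {
  stopifnot(inherits(s, "static_scenario"))
  s$n * level * scenario_nmb(s, level)
}

#' @rdname current_value
#' @export
perfect_value <- function(s) {
  stopifnot(inherits(s, "static_scenario"))
  s$n * (scenario_nmb(s, 1) - s$p * scenario_nmb(s, s$p))
}

#' @rdname current_value
#' @export
actual_value <- function(s) {
  stopifnot(inherits(s, "static_scenario"))
  s$n * (s$sigma * scenario_nmb(s, s$sigma) - s$p * scenario_nmb(s, s$p))
}

#' @rdname current_value
#' @export
net_value_of_strategy <- function(s) {
  actual_value(s) - s$strategy_cost
}

#' Summarise a static scenario
#'
#' @param object a [static_scenario()].
#' @param ... unused.
#' @return a one-row data frame with the current (before/after),
#'   perfect, actual and net values.
#' @export
summary.static_scenario <- function(object, ...) {
  data.frame(
    n = object$n, p = object$p, sigma = object$sigma,
    current_before = current_value(object),
    current_after = current_value(object, level = object$sigma),
    perfect = perfect_value(object),
    actual = actual_value(object),
    net_of_strategy = net_value_of_strategy(object)
  )
}
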