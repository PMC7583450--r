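# Implementation-dependent marginal cost/benefit profiles and the
# per-patient net monetary benefit (NMB) they induce.

#' Marginal cost/benefit profiles
#'
#' A `marginal_profile` describes the per-patient incremental health gain
#' \eqn{\Delta H(p)} (QALYs) and incremental cost \eqn{\Delta C(p)}
#' (currency) of a health technology as functions of the implementation
#' level \eqn{p \in [0, 1]}, i.e. the fraction of the eligible population
#' actually receiving the intervention. Three functional forms are
#' supported:
#'
#' * **constant** — \eqn{\Delta H} and \eqn{\Delta C} do not depend on
#'   `p` (the assumption of conventional cost-effectiveness analysis);
#' * **linear** — \eqn{\Delta H(p) = a_H p + b_H} and
#'   \eqn{\Delta C(p) = a_C p + b_C}, the form produced by
#'   [nmb_metamodel()]; a positive NMB slope means increasing returns to
#'   scale;
#' * **tabulated** — piecewise-linear interpolation through a set of
#'   `(p, value)` knots, with linear extrapolation from the end segments
#'   outside the knot range so the profile is defined on all of
#'   \eqn{[0, 1]}.
#'
#' Predicted values are deliberately not clamped to be non-negative: a
#' fitted line may give a slightly negative \eqn{\Delta H} near
#' \eqn{p = 0}, and clamping would distort downstream value arithmetic.
#'
#' @param delta_qaly,delta_cost constant per-patient incremental QALYs
#'   and cost (`constant_profile`), or numeric vectors of knot values
#'   (`tabulated_profile`).
#' @param health_slope,health_intercept coefficients of
#'   \eqn{\Delta H(p)} (QALY/patient per unit `p`; QALY/patient).
#' @param cost_slope,cost_intercept coefficients of \eqn{\Delta C(p)}
#'   (currency/patient per unit `p`; currency/patient).
#' @param p numeric vector of knot implementation levels in \eqn{[0,1]},
#'   strictly increasing (`tabulated_profile`).
#' @return an object of class `marginal_profile`.
#' @examples
#' linear_profile(0.1662, -0.006, -860, 1996)
#' constant_profile(0.1492, 1171)
#' tabulated_profile(c(0.03, 0.50, 0.92),
#'                   c(0.001, 0.0728, 0.1492),
#'                   c(1940, 1630, 1171))
#' @seealso [net_monetary_benefit()], [as_nmb_line()], [nmb_metamodel()]
#' @export
constant_profile <- function(delta_qaly, delta_cost) {
  stopifnot(is.numeric(delta_qaly), length(delta_qaly) == 1L, is.finite(delta_qaly),
            is.numeric(delta_cost), length(delta_cost) == 1L, is.finite(delta_cost))
  new_marginal_profile(
    health = list(kind = "constant", value = as.numeric(delta_qaly)),
    cost   = list(kind = "constant", value = as.numeric(delta_cost))
  )
}

#' @rdname constant_profile
#' @export
linear_profile <- function(health_slope, health_intercept, cost_slope, cost_intercept) {
  coefs <- c(health_slope, health_intercept, cost_slope, cost_intercept)
  stopifnot(is.numeric(coefs), length(coefs) == 4L, all(is.finite(coefs)))
  new_marginal_profile(
    health = list(kind = "linear", slope = as.numeric(health_slope),
                  intercept = as.numeric(health_intercept)),
    cost   = list(kind = "linear", slope = as.numeric(cost_slope),
                  intercept = as.numeric(cost_intercept))
  )
}

#' @rdname constant_profile
#' @export
tabulated_profile <- function(p, delta_qaly, delta_cost) {
  if (length(p) == 0L)
    stop("tabulated profile needs at least one knot", call. = FALSE)
  stopifnot(is.numeric(p), is.numeric(delta_qaly), is.numeric(delta_cost),
            length(delta_qaly) == length(p), length(delta_cost) == length(p))
  if (any(p < 0 | p > 1))
    stop("knot implementation levels must lie in [0, 1]", call. = FALSE)
  if (length(p) > 1L && any(diff(p) <= 0))
    stop("knot implementation levels must be strictly increasing", call. = FALSE)
  new_marginal_profile(
    health = list(kind = "tabulated", p = as.numeric(p), value = as.numeric(delta_qaly)),
    cost   = list(kind = "tabulated", p = as.numeric(p), value = as.numeric(delta_cost))
  )
}

new_marginal_profile <- function(health, cost) {
  structure(list(health = health, cost = cost), class = "marginal_profile")
}

is_marginal_profile <- function(x) inherits(x, "marginal_profile")

#' @export
print.marginal_profile <- function(x, ...) {
  cat("Marginal cost/benefit profile\n")
  cat("  ", format_component(x$health, "dH"), "\n", sep = "")
  cat("  ", format_component(x$cost, "dC"), "\n", sep = "")
  invisible(x)
}

format_component <- function(comp, label) {
  switch(comp$kind,
    constant  = sprintf("%s(p) = %g (constant)", label, comp$value),
    linear    = sprintf("%s(p) = %g p + %g", label, comp$slope, comp$intercept),
    tabulated = sprintf("%s(p): %d knots on [%g, %g], linear interpolation",
                        label, length(comp$p), min(comp$p), max(comp$p))
  )
}

check_level <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p))
    stop("implementation level must be numeric and non-missing", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("implementation level must lie in [0, 1]", call. = FALSE)
  as.numeric(p)
}

# Evaluate one profile component at levels p (already validated).
# Tabulated components interpolate between knots and extrapolate
# linearly from the nearest end segment.
eval_component <- function(comp, p) {
  switch(comp$kind,
    constant = rep_len(comp$value, length(p)),
    linear   = comp$slope * p + comp$intercept,
    tabulated = {
      kp <- comp$p; kv <- comp$value
      if (length(kp) == 1L) return(rep_len(kv, length(p)))
      out <- stats::approx(kp, kv, xout = pmin(pmax(p, kp[1L]), kp[length(kp)]))$y
      lo <- p < kp[1L]
      if (any(lo)) {
        s <- (kv[2L] - kv[1L]) / (kp[2L] - kp[1L])
        out[lo] <- kv[1L] + s * (p[lo] - kp[1L])
      }
      m <- length(kp)
      hi <- p > kp[m]
      if (any(hi)) {
        s <- (kv[m] - kv[m - 1L]) / (kp[m] - kp[m - 1L])
        out[hi] <- kv[m] + s * (p[hi] - kp[m])
      }
      out
    }
  )
}

#' Evaluate marginal incremental benefits and costs
#'
#' `marginal_health()` returns the per-patient incremental health gain
#' \eqn{\Delta H(p)} in QALYs; `marginal_cost()` returns the per-patient
#' incremental cost \eqn{\Delta C(p)} in currency units.
#'
#' @param profile a [marginal_profile][constant_profile].
#' @param p implementation level(s) in \eqn{[0, 1]}; vectorised.
#' @return numeric vector the length of `p`.
#' @examples
#' prof <- linear_profile(0.1662, -0.006, -860, 1996)
#' marginal_health(prof, 0.5)  # 0.0771
#' marginal_cost(prof, 0.5)    # 1566
#' @export
marginal_health <- function(profile, p) {
  stopifnot(is_marginal_profile(profile))
  eval_component(profile$health, check_level(p))
}

#' @rdname marginal_health
#' @export
marginal_cost <- function(profile, p) {
  stopifnot(is_marginal_profile(profile))
  eval_component(profile$cost, check_level(p))
}

#' Cost-effectiveness threshold
#'
#' The willingness-to-pay threshold \eqn{k} (currency per QALY) that
#' monetises health gains. The currency label is cosmetic; all
#' arithmetic is unit-agnostic.
#'
#' @param k threshold value, currency per QALY; must be positive.
#' @param currency free-text currency label used in printed output.
#' @return an object of class `threshold_policy`.
#' @examples
#' threshold_policy(20000, "EUR")
#' @export
threshold_policy <- function(k, currency = "EUR") {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) stop("threshold k must be positive", call. = FALSE)
  structure(list(k = as.numeric(k), currency = as.character(currency)),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("Cost-effectiveness threshold: %g %s per QALY\n", x$k, x$currency))
  invisible(x)
}

as_threshold <- function(threshold) {
  if (inherits(threshold, "threshold_policy")) return(threshold)
  threshold_policy(threshold)
}

#' Per-patient net monetary benefit
#'
#' Computes the implementation-dependent per-patient net monetary
#' benefit \eqn{NMB(p) = k\,\Delta H(p) - \Delta C(p)}. For a constant
#' profile the result does not depend on `p`.
#'
#' @inheritParams marginal_health
#' @param threshold a [threshold_policy()] (or a bare positive number,
#'   interpreted as `k`).
#' @return numeric vector of per-patient NMB values, in currency units.
#' @examples
#' prof <- linear_profile(0.1662, -0.006, -860, 1996)
#' net_monetary_benefit(prof, threshold_policy(20000), c(0.2, 0.6))
#' @export
net_monetary_benefit <- function(profile, threshold, p) {
  threshold <- as_threshold(threshold)
  threshold$k * marginal_health(profile, p) - marginal_cost(profile, p)
}

#' Net-monetary-benefit line
#'
#' A linear per-patient NMB function of the implementation level,
#' \eqn{NMB(p) = slope \cdot p + intercept}. A positive slope indicates
#' increasing returns to scale. `as_nmb_line()` derives the line induced
#' by a linear (or constant) profile at a given threshold:
#' slope \eqn{= k a_H - a_C}, intercept \eqn{= k b_H - b_C}.
#'
#' @param slope currency/patient per unit of implementation level.
#' @param intercept currency/patient at `p = 0`.
#' @return an object of class `nmb_line`.
#' @examples
#' as_nmb_line(linear_profile(0.1662, -0.006, -860, 1996),
#'             threshold_policy(20000))  # NMB(p) = 4184 p - 2116
#' @export
nmb_line <- function(slope, intercept) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept)),
            class = "nmb_line")
}

#' @rdname nmb_line
#' @inheritParams net_monetary_benefit
#' @export
as_nmb_line <- function(profile, threshold) {
  stopifnot(is_marginal_profile(profile))
  threshold <- as_threshold(threshold)
  comp_line <- function(comp) {
    switch(comp$kind,
      constant = c(slope = 0, intercept = comp$value),
      linear   = c(slope = comp$slope, intercept = comp$intercept),
      stop("only constant or linear profiles induce an NMB line; ",
           "use net_monetary_benefit() for tabulated profiles", call. = FALSE)
    )
  }
  h <- comp_line(profile$health)
  cst <- comp_line(profile$cost)
  nmb_line(threshold$k * h[["slope"]] - cst[["slope"]],
           threshold$k * h[["intercept"]] - cst[["intercept"]])
}

#' @export
print.nmb_line <- function(x, ...) {
  cat(sprintf("NMB(p) = %g p %s %g per patient\n",
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept)))
  invisible(x)
}

#' @param object an `nmb_line`.
#' @param p implementation level(s); unrestricted for a line.
#' @param ... unused.
#' @rdname nmb_line
#' @export
predict.nmb_line <- function(object, p, ...) {
  object$slope * as.numeric(p) + object$intercept
}
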