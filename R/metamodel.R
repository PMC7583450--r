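# OLS meta-model: linear emulation of decision-model outputs as a
# function of the implementation level, and the break-even solver.

#' Fit a linear meta-model of marginal costs and benefits
#'
#' Fits ordinary-least-squares lines (with intercept, unweighted)
#' through decision-model output triples `(p, delta_qaly, delta_cost)`,
#' giving the per-patient incremental QALYs \eqn{\Delta H(p)} and
#' incremental cost \eqn{\Delta C(p)} as linear functions of the
#' implementation level `p`. The fitted lines act as a cheap emulator
#' ("meta-model") of the underlying decision-analytic model, and
#' together with a threshold induce a linear net-monetary-benefit
#' function via [as_nmb_line()].
#'
#' Coefficients are carried at full precision. For reporting, and for
#' reproducing published case-study arithmetic that uses rounded
#' coefficients, [as_linear_profile()] can round the health
#' coefficients to 4 decimal places and the cost coefficients to whole
#' currency units.
#'
#' @param data a data frame with numeric columns `p`, `delta_qaly` and
#'   `delta_cost` (one row per decision-model run), such as the one
#'   returned by [read_marginal_triples()]. At least two rows with
#'   distinct `p` are required.
#' @return an object of class `nmb_metamodel` with components
#'   `coefficients` (2x2 matrix, rows `health`/`cost`, columns
#'   `slope`/`intercept`), `r.squared` (named vector), the underlying
#'   `lm` fits, and the input `data`.
#' @examples
#' fit <- nmb_metamodel(data.frame(
#'   p = c(0.03, 0.50, 0.92),
#'   delta_qaly = c(0.001, 0.0728, 0.1492),
#'   delta_cost = c(1940, 1630, 1171)))
#' coef(fit)
#' summary(fit)
#' @seealso [break_even()], [as_linear_profile()]
#' @export
nmb_metamodel <- function(data) {
  required <- c("p", "delta_qaly", "delta_cost")
  if (!is.data.frame(data) || !all(required %in% names(data)))
    stop("data must be a data frame with columns p, delta_qaly, delta_cost",
         call. = FALSE)
  data <- data[required]
  if (anyNA(data) || !all(vapply(data, is.numeric, logical(1L))))
    stop("p, delta_qaly and delta_cost must be numeric and non-missing",
         call. = FALSE)
  check_level(data$p)
  if (length(unique(data$p)) < 2L)
    stop("degenerate fit: need at least 2 distinct implementation levels",
         call. = FALSE)

  fit_h <- stats::lm(delta_qaly ~ p, data = data)
  fit_c <- stats::lm(delta_cost ~ p, data = data)

  coefs <- rbind(
    health = rev(unname(stats::coef(fit_h))),
    cost   = rev(unname(stats::coef(fit_c)))
  )
  colnames(coefs) <- c("slope", "intercept")

  structure(list(
    coefficients = coefs,
    r.squared = c(health = r_squared(fit_h), cost = r_squared(fit_c)),
    fit_health = fit_h,
    fit_cost = fit_c,
    data = data
  ), class = "nmb_metamodel")
}

# R^2 = 1 - SSres/SStot; errors on zero total sum of squares rather
# than returning lm's convention of 0.
r_squared <- function(fit) {
  y <- fit$model[[1L]]
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0)
    stop("undefined R-squared: response has zero total sum of squares",
         call. = FALSE)
  1 - sum(stats::residuals(fit)^2) / sstot
}

#' @export
print.nmb_metamodel <- function(x, digits = 4L, ...) {
  cf <- x$coefficients
  cat("Linear meta-model of marginal incremental costs and benefits\n")
  cat(sprintf("  dH(p) = %s p + %s   (R-squared %.3f)\n",
              format(cf["health", "slope"], digits = digits),
              format(cf["health", "intercept"], digits = digits),
              x$r.squared[["health"]]))
  cat(sprintf("  dC(p) = %s p + %s   (R-squared %.3f)\n",
              format(cf["cost", "slope"], digits = digits),
              format(cf["cost", "intercept"], digits = digits),
              x$r.squared[["cost"]]))
  cat(sprintf("  fitted to %d decision-model runs, p in [%g, %g]\n",
              nrow(x$data), min(x$data$p), max(x$data$p)))
  invisible(x)
}

#' @export
coef.nmb_metamodel <- function(object, ...) object$coefficients

#' @export
residuals.nmb_metamodel <- function(object, ...) {
  cbind(health = stats::residuals(object$fit_health),
        cost   = stats::residuals(object$fit_cost))
}

#' Predict from a fitted meta-model
#'
#' Evaluates the fitted \eqn{\Delta H(p)}, \eqn{\Delta C(p)} or, given a
#' threshold, the induced net monetary benefit
#' \eqn{k\,\Delta H(p) - \Delta C(p)} at new implementation levels.
#'
#' @param object an [nmb_metamodel()] fit.
#' @param p implementation level(s) in \eqn{[0, 1]}. The fitted lines
#'   are valid on all of \eqn{[0, 1]}, including outside the range of
#'   the fitting data.
#' @param component one of `"health"`, `"cost"`, `"nmb"`.
#' @param threshold a [threshold_policy()]; required for
#'   `component = "nmb"`.
#' @param ... unused.
#' @return numeric vector the length of `p`.
#' @export
predict.nmb_metamodel <- function(object, p, component = c("health", "cost", "nmb"),
                                  threshold = NULL, ...) {
  component <- match.arg(component)
  p <- check_level(p)
  cf <- object$coefficients
  h <- cf["health", "slope"] * p + cf["health", "intercept"]
  cst <- cf["cost", "slope"] * p + cf["cost", "intercept"]
  switch(component,
    health = h,
    cost = cst,
    nmb = {
      if (is.null(threshold))
        stop("component = \"nmb\" needs a threshold", call. = FALSE)
      as_threshold(threshold)$k * h - cst
    })
}

#' @export
summary.nmb_metamodel <- function(object, ...) {
  structure(list(fit = object), class = "summary.nmb_metamodel")
}

#' @export
print.summary.nmb_metamodel <- function(x, ...) {
  print(x$fit)
  res <- residuals(x$fit)
  cat("\nResiduals:\n")
  print(signif(res, 3L))
  invisible(x)
}

#' Extract a linear profile from a meta-model fit
#'
#' Converts an [nmb_metamodel()] fit into a [linear_profile()]. With
#' `rounded = TRUE` (the default used by the packaged case study) the
#' health coefficients are rounded to 4 decimal places and the cost
#' coefficients to whole currency units, matching the precision at
#' which such coefficients are conventionally reported; published
#' downstream tables are exact consequences of the rounded line.
#'
#' @param fit an [nmb_metamodel()] fit.
#' @param rounded logical; round coefficients for reporting-grade
#'   arithmetic (`TRUE`) or keep full precision (`FALSE`).
#' @return a [linear_profile()].
#' @export
as_linear_profile <- function(fit, rounded = TRUE) {
  stopifnot(inherits(fit, "nmb_metamodel"))
  cf <- fit$coefficients
  if (rounded) {
    linear_profile(round(cf["health", "slope"], 4L), round(cf["health", "intercept"], 4L),
                   round(cf["cost", "slope"], 0L), round(cf["cost", "intercept"], 0L))
  } else {
    linear_profile(cf["health", "slope"], cf["health", "intercept"],
                   cf["cost", "slope"], cf["cost", "intercept"])
  }
}

#' Plot a meta-model fit
#'
#' Two panels: the decision-model triples with the fitted
#' \eqn{\Delta H(p)} and \eqn{\Delta C(p)} lines overlaid.
#'
#' @param x an [nmb_metamodel()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nmb_metamodel <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  grid <- seq(0, 1, length.out = 101L)
  cf <- x$coefficients
  graphics::plot(x$data$p, x$data$delta_qaly, xlim = c(0, 1),
                 xlab = "implementation level p",
                 ylab = "incremental QALYs per patient", ...)
  graphics::lines(grid, cf["health", "slope"] * grid + cf["health", "intercept"])
  graphics::plot(x$data$p, x$data$delta_cost, xlim = c(0, 1),
                 xlab = "implementation level p",
                 ylab = "incremental cost per patient", ...)
  graphics::lines(grid, cf["cost", "slope"] * grid + cf["cost", "intercept"])
  invisible(x)
}

#' Break-even implementation level
#'
#' Finds the implementation level \eqn{p^*} at which the per-patient net
#' monetary benefit crosses zero: below \eqn{p^*} the technology is not
#' a cost-effective use of resources at the stated threshold, above it
#' it is (for increasing returns to scale). For a linear NMB function
#' the root is closed-form; for general profiles the zero is bracketed
#' on a grid over \eqn{[0, 1]} and refined with [stats::uniroot()] to
#' tolerance `1e-9`. If the NMB never changes sign the result carries
#' the sentinel `"always_cost_effective"` (NMB positive throughout) or
#' `"never_cost_effective"` (non-positive throughout). When a tabulated
#' profile crosses zero more than once the smallest root is returned
#' and `multiple_roots` is flagged.
#'
#' @param x an [nmb_line()], a [marginal_profile][constant_profile], or
#'   an [nmb_metamodel()] fit.
#' @param threshold a [threshold_policy()] (not needed for an
#'   `nmb_line`, which is already monetised).
#' @param rounded for a meta-model fit: use the rounded-coefficient
#'   line (see [as_linear_profile()]).
#' @param ... passed to methods.
#' @return an object of class `break_even_result` with fields `level`
#'   (numeric root, or `NA` with a `status` sentinel),
#'   `rounded_percent` (smallest whole percent with strictly positive
#'   NMB, when defined), `status`, and `multiple_roots`.
#' @examples
#' break_even(nmb_line(4184, -2116))  # 0.5057..., 51%
#' @export
break_even <- function(x, ...) UseMethod("break_even")

new_break_even <- function(level, status, nmb_fun, multiple_roots = FALSE) {
  rounded_percent <- NA_integer_
  if (status == "crosses_zero") {
    pos <- which(nmb_fun((0:100) / 100) > 0)
    if (length(pos)) rounded_percent <- pos[1L] - 1L
  } else if (status == "always_cost_effective") {
    rounded_percent <- 0L
  }
  structure(list(level = level, status = status,
                 rounded_percent = rounded_percent,
                 multiple_roots = multiple_roots),
            class = "break_even_result")
}

#' @rdname break_even
#' @export
break_even.nmb_line <- function(x, ...) {
  f <- function(p) predict(x, p)
  if (x$slope == 0) {
    status <- if (x$intercept > 0) "always_cost_effective" else "never_cost_effective"
    return(new_break_even(NA_real_, status, f))
  }
  root <- -x$intercept / x$slope
  if (root <= 0 || root >= 1) {
    v <- f(c(0, 1))
    status <- if (all(v > 0)) "always_cost_effective"
              else if (all(v <= 0)) "never_cost_effective"
              else "crosses_zero"  # root at an endpoint
    lev <- if (status == "crosses_zero") min(max(root, 0), 1) else NA_real_
    return(new_break_even(lev, status, f))
  }
  new_break_even(root, "crosses_zero", f)
}

#' @rdname break_even
#' @export
break_even.marginal_profile <- function(x, threshold, ...) {
  threshold <- as_threshold(threshold)
  if (x$health$kind != "tabulated" && x$cost$kind != "tabulated")
    return(break_even(as_nmb_line(x, threshold)))
  f <- function(p) net_monetary_benefit(x, threshold, p)
  # bracket sign changes on the knot grid plus endpoints
  grid <- sort(unique(c(0, 1, x$health$p, x$cost$p)))
  v <- f(grid)
  sign_change <- which(v[-length(v)] * v[-1L] < 0)
  exact_zero <- which(v == 0)
  if (!length(sign_change) && !length(exact_zero)) {
    status <- if (all(v > 0)) "always_cost_effective" else "never_cost_effective"
    return(new_break_even(NA_real_, status, f))
  }
  roots <- grid[exact_zero]
  for (i in sign_change) {
    roots <- c(roots, stats::uniroot(f, lower = grid[i], upper = grid[i + 1L],
                                     tol = 1e-9)$root)
  }
  roots <- sort(roots)
  new_break_even(roots[1L], "crosses_zero", f,
                 multiple_roots = length(roots) > 1L)
}

#' @rdname break_even
#' @export
break_even.nmb_metamodel <- function(x, threshold, rounded = TRUE, ...) {
  break_even(as_nmb_line(as_linear_profile(x, rounded = rounded), threshold))
}

#' @export
print.break_even_result <- function(x, ...) {
  if (x$status == "crosses_zero") {
    cat(sprintf("Break-even implementation level: %.4f (NMB > 0 from %d%%)\n",
                x$level, x$rounded_percent))
    if (x$multiple_roots)
      cat("  note: NMB crosses zero more than once; smallest root reported\n")
  } else {
    cat(sprintf("No break-even level: %s on [0, 1]\n",
                gsub("_", " ", x$status)))
  }
  invisible(x)
}

#' Read decision-model output triples
#'
#' Reads a delimited file with header columns `p`, `delta_qaly`,
#' `delta_cost` ("." decimal separator) into the data frame expected by
#' [nmb_metamodel()].
#'
#' @param path path to a CSV file.
#' @return a data frame with columns `p`, `delta_qaly`, `delta_cost`.
#' @export
read_marginal_triples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("p", "delta_qaly", "delta_cost")
  if (!all(required %in% names(df)))
    stop("file must have header columns p, delta_qaly, delta_cost", call. = FALSE)
  df[required]
}
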