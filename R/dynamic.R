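# Multi-year discounted value-of-implementation streams with diffusion.

#' Discounting specification
#'
#' Annual discount rate plus the exponent convention. Published
#' analyses differ on whether the first year is discounted:
#' `"first_year_undiscounted"` divides year `t` by \eqn{(1+r)^{t-1}}
#' (year 1 at face value); `"first_year_discounted"` divides by
#' \eqn{(1+r)^t}. The convention is always explicit because it silently
#' changes every yearly value by a factor of \eqn{1+r}.
#'
#' @param rate annual discount rate as a fraction (e.g. `0.03`); >= 0.
#' @param convention `"first_year_undiscounted"` or
#'   `"first_year_discounted"`.
#' @return an object of class `discount_spec`.
#' @examples
#' discount_factor(1:3, discount_spec(0.03))
#' @export
discount_spec <- function(rate = 0.03,
                          convention = c("first_year_undiscounted",
                                         "first_year_discounted")) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  convention <- match.arg(convention)
  structure(list(rate = as.numeric(rate), convention = convention),
            class = "discount_spec")
}

#' @export
print.discount_spec <- function(x, ...) {
  cat(sprintf("Discounting: %g%% per year, %s\n", 100 * x$rate,
              gsub("_", " ", x$convention)))
  invisible(x)
}

#' @rdname discount_spec
#' @param t year index (integer >= 1); vectorised.
#' @param spec a `discount_spec`.
#' @return `discount_factor()`: the unitless present-value factor(s)
#'   for year `t`.
#' @export
discount_factor <- function(t, spec) {
  stopifnot(inherits(spec, "discount_spec"))
  if (!is.numeric(t) || any(t < 1) || any(t != floor(t)))
    stop("year index t must be an integer >= 1", call. = FALSE)
  expo <- switch(spec$convention,
                 first_year_undiscounted = t - 1,
                 first_year_discounted = t)
  (1 + spec$rate)^(-expo)
}

#' Linear diffusion path
#'
#' Year-on-year uptake path under linear diffusion:
#' \eqn{p_t = \min(1, start + step (t - 1))} for `t = 1..horizon`.
#' Values are capped at 1 so an arithmetic construction cannot leave
#' the unit interval.
#'
#' @param start uptake in year 1, in \eqn{[0, 1]}.
#' @param step additional uptake per year (fraction; 6 percentage
#'   points per year is `0.06`).
#' @param horizon number of years (integer >= 1).
#' @return numeric vector of length `horizon`.
#' @examples
#' linear_diffusion(0.09, 0.06, 15)
#' @export
linear_diffusion <- function(start, step, horizon) {
  check_level(start)
  stopifnot(length(start) == 1L, is.numeric(step), length(step) == 1L,
            is.numeric(horizon), length(horizon) == 1L, horizon >= 1,
            horizon == floor(horizon))
  pmin(1, pmax(0, start + step * (seq_len(horizon) - 1)))
}

#' Multi-year implementation schedules
#'
#' The per-year inputs of a dynamic value-of-implementation analysis:
#' population, baseline uptake path, strategy uptake path and strategy
#' cost stream. Scalars are broadcast across the horizon.
#'
#' @param horizon number of years T (integer >= 1).
#' @param population eligible patients per year; scalar or length-T
#'   vector.
#' @param baseline baseline uptake path \eqn{p_t}; scalar or length-T
#'   vector with values in \eqn{[0, 1]}.
#' @param strategy uptake path \eqn{\sigma_t} under the implementation
#'   strategy; scalar, length-T vector, or `NULL` when no strategy is
#'   modelled.
#' @param costs strategy cost per year \eqn{i_t} (currency, >= 0);
#'   scalar or length-T vector.
#' @return an object of class `schedule_set`.
#' @export
schedule_set <- function(horizon, population, baseline, strategy = NULL, costs = 0) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon >= 1,
            horizon == floor(horizon))
  horizon <- as.integer(horizon)
  bc <- function(x, what) {
    if (length(x) == 1L) x <- rep_len(x, horizon)
    if (length(x) != horizon)
      stop(sprintf("%s must be a scalar or a vector of length %d", what, horizon),
           call. = FALSE)
    as.numeric(x)
  }
  population <- bc(population, "population")
  baseline <- check_level(bc(baseline, "baseline"))
  if (!is.null(strategy)) strategy <- check_level(bc(strategy, "strategy"))
  costs <- bc(costs, "costs")
  if (any(population < 0)) stop("population must be >= 0", call. = FALSE)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  structure(list(horizon = horizon, population = population,
                 baseline = baseline, strategy = strategy, costs = costs),
            class = "schedule_set")
}

#' @export
print.schedule_set <- function(x, ...) {
  cat(sprintf("Schedules over %d years: population %s, baseline uptake %.2f -> %.2f%s\n",
              x$horizon,
              if (length(unique(x$population)) == 1L) format(x$population[1L])
              else "per-year",
              x$baseline[1L], x$baseline[x$horizon],
              if (is.null(x$strategy)) "" else
                sprintf(", strategy uptake %.2f -> %.2f",
                        x$strategy[1L], x$strategy[x$horizon])))
  invisible(x)
}

# Coerce `profile` (a marginal_profile or a named list of them) to a
# named list; single profiles get the column name "value".
profile_list <- function(profile) {
  if (is_marginal_profile(profile)) return(list(value = profile))
  if (!is.list(profile) || !length(profile) ||
      !all(vapply(profile, is_marginal_profile, logical(1L))))
    stop("profile must be a marginal_profile or a named list of them",
         call. = FALSE)
  if (is.null(names(profile)) || any(!nzchar(names(profile))))
    stop("a list of profiles must be fully named", call. = FALSE)
  profile
}

new_value_table <- function(years, p, sigma, df, values, spec) {
  tab <- data.frame(year = years, p = p)
  if (!is.null(sigma)) tab$sigma <- sigma
  tab$discount_factor <- df
  for (nm in names(values)) tab[[nm]] <- values[[nm]]
  structure(tab,
            class = c("voimp_value_table", "data.frame"),
            value_columns = names(values),
            totals = vapply(values, sum, numeric(1L)),
            rate = spec$rate,
            convention = spec$convention)
}

make_stream <- function(s, profile, threshold, spec, yearly_fun, need_strategy = FALSE) {
  stopifnot(inherits(s, "schedule_set"), inherits(spec, "discount_spec"))
  threshold <- as_threshold(threshold)
  if (need_strategy && is.null(s$strategy))
    stop("this value stream needs a strategy uptake path in the schedule_set",
         call. = FALSE)
  profiles <- profile_list(profile)
  years <- seq_len(s$horizon)
  df <- discount_factor(years, spec)
  values <- lapply(profiles, function(pr) {
    nmb <- function(p) net_monetary_benefit(pr, threshold, p)
    yearly_fun(s, nmb) * df
  })
  new_value_table(years, s$baseline,
                  if (need_strategy) s$strategy else NULL,
                  df, values, spec)
}

#' Dynamic value-of-implementation streams
#'
#' Discounted per-year population value streams, each returned as a
#' [value table][cumulative_value] with one value column per supplied
#' profile:
#'
#' * `current_value_stream()` — value of the uptake actually occurring:
#'   \eqn{n_t\,p_t\,NMB(p_t)} each year;
#' * `perfect_value_stream()` — value forgone relative to full uptake:
#'   \eqn{n_t (NMB(1) - p_t\,NMB(p_t))};
#' * `actual_value_stream()` — value of an implementation strategy
#'   moving uptake from \eqn{p_t} to \eqn{\sigma_t}:
#'   \eqn{n_t (\sigma_t NMB(\sigma_t) - p_t NMB(p_t))};
#' * `net_value_stream()` — the actual value minus the yearly strategy
#'   cost \eqn{i_t}, i.e. \eqn{n_t(\sigma_t NMB(\sigma_t) - p_t NMB(p_t)) - i_t},
#'   discounted.
#'
#' Each yearly quantity is multiplied by the year's discount factor;
#' column totals are stored as the `totals` attribute and shown by the
#' print method.
#'
#' @param s a [schedule_set()].
#' @param profile a [marginal_profile][constant_profile], or a named
#'   list of profiles to compute several columns side by side (e.g.
#'   `list(constant = ..., varying = ...)`).
#' @param threshold a [threshold_policy()].
#' @param spec a [discount_spec()].
#' @return a `voimp_value_table`: a data frame with columns `year`,
#'   `p`, (`sigma`,) `discount_factor` and one discounted value column
#'   per profile, plus `totals`, `rate` and `convention` attributes.
#' @examples
#' sched <- schedule_set(15, 10000, linear_diffusion(0.09, 0.06, 15))
#' current_value_stream(sched, constant_profile(0.1492, 1171),
#'                      threshold_policy(20000),
#'                      discount_spec(0.03, "first_year_discounted"))
#' @export
current_value_stream <- function(s, profile, threshold, spec) {
  make_stream(s, profile, threshold, spec,
              function(s, nmb) s$population * s$baseline * nmb(s$baseline))
}

#' @rdname current_value_stream
#' @export
perfect_value_stream <- function(s, profile, threshold, spec) {
  make_stream(s, profile, threshold, spec,
              function(s, nmb) s$population * (nmb(1) - s$baseline * nmb(s$baseline)))
}

#' @rdname current_value_stream
#' @export
actual_value_stream <- function(s, profile, threshold, spec) {
  make_stream(s, profile, threshold, spec,
              function(s, nmb) s$population *
                (s$strategy * nmb(s$strategy) - s$baseline * nmb(s$baseline)),
              need_strategy = TRUE)
}

#' @rdname current_value_stream
#' @export
net_value_stream <- function(s, profile, threshold, spec) {
  make_stream(s, profile, threshold, spec,
              function(s, nmb) s$population *
                (s$strategy * nmb(s$strategy) - s$baseline * nmb(s$baseline)) -
                s$costs,
              need_strategy = TRUE)
}

value_columns <- function(table) attr(table, "value_columns")

#' @export
print.voimp_value_table <- function(x, digits = 0L, ...) {
  cat(sprintf("Discounted value stream (%g%% per year, %s)\n",
              100 * attr(x, "rate"), gsub("_", " ", attr(x, "convention"))))
  shown <- as.data.frame(x)
  for (nm in value_columns(x)) shown[[nm]] <- round(shown[[nm]], digits)
  total <- shown[1L, ]
  total[] <- NA
  total$year <- NA
  for (nm in value_columns(x)) total[[nm]] <- round(attr(x, "totals")[[nm]], digits)
  rownames(total) <- "Total"
  print(rbind(shown, total))
  invisible(x)
}

#' Window sums and totals of a value stream
#'
#' Sums a value column of a [value table][current_value_stream] over an
#' inclusive window of years. The full window reproduces the stored
#' column total.
#'
#' @param table a `voimp_value_table`.
#' @param from_year,to_year inclusive year window (defaults: the whole
#'   horizon).
#' @param column which value column to sum; defaults to the first.
#' @return a single currency value (already discounted).
#' @export
cumulative_value <- function(table, from_year = 1L, to_year = max(table$year),
                             column = value_columns(table)[1L]) {
  stopifnot(inherits(table, "voimp_value_table"))
  if (!column %in% value_columns(table))
    stop(sprintf("no value column %s; available: %s", column,
                 paste(value_columns(table), collapse = ", ")), call. = FALSE)
  if (from_year < 1L || to_year > max(table$year) || from_year > to_year)
    stop("year window outside the table horizon", call. = FALSE)
  sum(table[[column]][table$year >= from_year & table$year <= to_year])
}

#' Health opportunity cost of a monetary loss
#'
#' Converts a monetary loss into the QALYs that the same resources
#' could have bought elsewhere in the health system at the threshold:
#' \eqn{|loss| / k}.
#'
#' @param loss a currency amount (sign ignored).
#' @param threshold a [threshold_policy()].
#' @return QALYs.
#' @examples
#' qaly_equivalent(-12896324, threshold_policy(20000))  # ~645
#' @export
qaly_equivalent <- function(loss, threshold) {
  abs(loss) / as_threshold(threshold)$k
}

#' Plot a value stream
#'
#' Line plot of each discounted value column against the year.
#'
#' @param x a `voimp_value_table`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.voimp_value_table <- function(x, ...) {
  cols <- value_columns(x)
  y <- as.matrix(as.data.frame(x)[cols])
  graphics::matplot(x$year, y, type = "b", pch = seq_along(cols), lty = 1L,
                    xlab = "year", ylab = "discounted value", ...)
  graphics::abline(h = 0, lty = 3L)
  if (length(cols) > 1L)
    graphics::legend("topleft", legend = cols, pch = seq_along(cols),
                     col = seq_along(cols), lty = 1L, bty = "n")
  invisible(x)
}
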