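# Packaged MammaPrint case study: a 70-gene breast-cancer recurrence
# test whose marginal incremental costs fall, and benefits rise, as
# clinician uptake improves. All constants ship as plain-text files
# under inst/extdata.

#' MammaPrint case-study inputs
#'
#' Returns the packaged inputs of the MammaPrint worked example: the
#' three decision-model output triples (implementation level,
#' incremental QALYs/patient, incremental cost/patient), the threshold
#' of 20,000 EUR per QALY, an eligible population of 10,000 women per
#' year, linear diffusion from 9% uptake at 6 percentage points per
#' year over a 15-year horizon, an implementation strategy adding 3
#' percentage points of uptake, a 3% annual discount rate, and the
#' discount convention pinned for each dynamic stream.
#'
#' The constant-NMB comparator is built from the highest tabulated
#' implementation level (92%): conventional cost-effectiveness
#' analysis reports long-run values, best represented by the marginal
#' costs and benefits closest to full implementation.
#'
#' @return a list of class `mammaprint_inputs` with components
#'   `triples` (data frame), `threshold`, `population`, `static`
#'   (baseline/strategy level pairs), and `dynamic` (horizon, diffusion
#'   start/step, strategy offset, rate, per-stream conventions).
#' @examples
#' inp <- mammaprint_inputs()
#' inp$triples
#' @export
mammaprint_inputs <- function() {
  triples <- read_marginal_triples(
    system.file("extdata", "mammaprint_marginals.csv", package = "voimp",
                mustWork = TRUE))
  cfg <- jsonlite::read_json(
    system.file("extdata", "mammaprint_scenario.json", package = "voimp",
                mustWork = TRUE), simplifyVector = TRUE)
  structure(list(
    triples = triples,
    threshold = threshold_policy(cfg$threshold$k, cfg$threshold$currency),
    population = cfg$population,
    static = cfg$static,
    dynamic = cfg$dynamic
  ), class = "mammaprint_inputs")
}

#' @export
print.mammaprint_inputs <- function(x, ...) {
  cat("MammaPrint case-study inputs\n")
  print(x$triples)
  print(x$threshold)
  cat(sprintf("Population %g/year; diffusion %g + %g/year over %d years; strategy +%g; rate %g\n",
              x$population, x$dynamic$diffusion_start, x$dynamic$diffusion_step,
              x$dynamic$horizon, x$dynamic$strategy_offset, x$dynamic$rate))
  invisible(x)
}

# The two NMB assumptions compared throughout the case study:
# constant (92% row of the triples) and varying (rounded meta-model line).
mammaprint_profiles <- function(inputs = mammaprint_inputs()) {
  tr <- inputs$triples
  top <- which.max(tr$p)
  list(
    constant = constant_profile(tr$delta_qaly[top], tr$delta_cost[top]),
    varying = as_linear_profile(nmb_metamodel(tr), rounded = TRUE)
  )
}

#' Case-study static value table
#'
#' Single-period value-of-implementation results for the MammaPrint
#' example: current value before and after an implementation strategy,
#' and the actual value of the strategy, for each baseline/final level
#' pair (20%→40% and 40%→60%) under both the constant-NMB and the
#' varying-NMB assumption.
#'
#' @param inputs case-study inputs, from [mammaprint_inputs()].
#' @return a data frame with one row per (NMB assumption, level pair)
#'   and columns `nmb`, `p`, `sigma`, `current_before`,
#'   `current_after`, `actual` (currency).
#' @examples
#' mammaprint_static_table()
#' @export
mammaprint_static_table <- function(inputs = mammaprint_inputs()) {
  profs <- mammaprint_profiles(inputs)
  pairs <- data.frame(p = inputs$static$baseline_levels,
                      sigma = inputs$static$strategy_levels)
  rows <- lapply(names(profs), function(nm) {
    cbind(nmb = nm, do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      s <- static_scenario(inputs$population, pairs$p[i], pairs$sigma[i],
                           profile = profs[[nm]], threshold = inputs$threshold)
      data.frame(p = s$p, sigma = s$sigma,
                 current_before = current_value(s),
                 current_after = current_value(s, level = s$sigma),
                 actual = actual_value(s))
    })))
  })
  do.call(rbind, rows)
}

mammaprint_schedule <- function(inputs, with_strategy = FALSE) {
  d <- inputs$dynamic
  base <- linear_diffusion(d$diffusion_start, d$diffusion_step, d$horizon)
  schedule_set(d$horizon, inputs$population, base,
               strategy = if (with_strategy)
                 pmin(1, base + d$strategy_offset))
}

#' Case-study dynamic value streams
#'
#' `mammaprint_current_value_table()` is the discounted current value
#' of MammaPrint's diffusing uptake over 15 years (no strategy), with
#' year 1 discounted; `mammaprint_strategy_value_table()` is the
#' discounted actual value of an implementation strategy that adds 3
#' percentage points of uptake every year, with year 1 undiscounted.
#' Each table carries a `constant` and a `varying` NMB column.
#'
#' @inheritParams mammaprint_static_table
#' @return a [voimp_value_table][current_value_stream].
#' @examples
#' tab <- mammaprint_current_value_table()
#' attr(tab, "totals")
#' @export
mammaprint_current_value_table <- function(inputs = mammaprint_inputs()) {
  current_value_stream(
    mammaprint_schedule(inputs),
    mammaprint_profiles(inputs),
    inputs$threshold,
    discount_spec(inputs$dynamic$rate, inputs$dynamic$current_value_convention))
}

#' @rdname mammaprint_current_value_table
#' @export
mammaprint_strategy_value_table <- function(inputs = mammaprint_inputs()) {
  actual_value_stream(
    mammaprint_schedule(inputs, with_strategy = TRUE),
    mammaprint_profiles(inputs),
    inputs$threshold,
    discount_spec(inputs$dynamic$rate, inputs$dynamic$strategy_value_convention))
}

#' Case-study headline quantities
#'
#' The summary numbers of the MammaPrint example: the fitted NMB line,
#' the break-even uptake percent, the cumulative discounted loss over
#' the early years in which the varying-NMB current value is negative
#' (years 1–7), its QALY opportunity-cost equivalent, and the
#' difference between the strategy-value totals under the two NMB
#' assumptions.
#'
#' @inheritParams mammaprint_static_table
#' @param loss_years inclusive year window over which the early loss is
#'   accumulated.
#' @return a list of class `mammaprint_summary`.
#' @examples
#' mammaprint_headlines()
#' @export
mammaprint_headlines <- function(inputs = mammaprint_inputs(),
                                 loss_years = c(1L, 7L)) {
  fit <- nmb_metamodel(inputs$triples)
  line <- as_nmb_line(as_linear_profile(fit, rounded = TRUE), inputs$threshold)
  be <- break_even(line)
  cur <- mammaprint_current_value_table(inputs)
  loss <- cumulative_value(cur, loss_years[1L], loss_years[2L], "varying")
  strat_totals <- attr(mammaprint_strategy_value_table(inputs), "totals")
  structure(list(
    nmb_line = line,
    break_even_level = be$level,
    break_even_percent = be$rounded_percent,
    loss_years = loss_years,
    early_loss = loss,
    early_loss_qaly = qaly_equivalent(loss, inputs$threshold),
    current_value_totals = attr(cur, "totals"),
    strategy_value_totals = strat_totals,
    strategy_value_difference = strat_totals[["varying"]] - strat_totals[["constant"]]
  ), class = "mammaprint_summary")
}

#' @export
print.mammaprint_summary <- function(x, ...) {
  print(x$nmb_line)
  cat(sprintf("Break-even uptake: %.2f%% (first whole percent with NMB > 0: %d%%)\n",
              100 * x$break_even_level, x$break_even_percent))
  cat(sprintf("Cumulative discounted loss, years %d-%d: %s (= %.1f QALYs at the threshold)\n",
              x$loss_years[1L], x$loss_years[2L],
              format(round(x$early_loss), big.mark = ","), x$early_loss_qaly))
  cat(sprintf("15-year current value totals: constant %s, varying %s\n",
              format(round(x$current_value_totals[["constant"]]), big.mark = ","),
              format(round(x$current_value_totals[["varying"]]), big.mark = ",")))
  cat(sprintf("15-year strategy value totals: constant %s, varying %s (difference %s)\n",
              format(round(x$strategy_value_totals[["constant"]]), big.mark = ","),
              format(round(x$strategy_value_totals[["varying"]]), big.mark = ","),
              format(round(x$strategy_value_difference), big.mark = ",")))
  invisible(x)
}
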