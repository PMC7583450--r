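# Declarative scenario configuration (YAML/JSON) and tabular writers.

#' Load and validate a scenario configuration
#'
#' Reads a declarative scenario description from a YAML or JSON file
#' and validates it. A configuration has a `threshold` block (`k`,
#' optional `currency`), a `profile` block (see below), and a `static`
#' and/or `dynamic` block; validation errors name the offending field.
#'
#' Profile kinds:
#' * `constant`: `delta_qaly`, `delta_cost`;
#' * `linear`: `health_slope`, `health_intercept`, `cost_slope`,
#'   `cost_intercept`;
#' * `tabulated`: vectors `p`, `delta_qaly`, `delta_cost`;
#' * `fit`: `path` to a triples CSV (see [read_marginal_triples()]),
#'   optional `rounded` (default `TRUE`), fitted with
#'   [nmb_metamodel()] at load time.
#'
#' Static block: `n`, `p`, optional `sigma` (default `p`) and
#' `strategy_cost` (default 0). Dynamic block: `horizon`, `population`,
#' either `diffusion: {start, step}` or an explicit `baseline` path,
#' optionally `strategy_offset` or an explicit `strategy` path, a
#' `costs` scalar/vector (default 0), `rate` (default 0.03) and
#' `convention` (default `"first_year_undiscounted"`, matching the
#' convention under which year 1 is valued at face value).
#'
#' In YAML configs quote the population key (`"n":`): a bare `n` is
#' YAML-1.1 shorthand for a boolean and would not be recognised.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated list of class `scenario_config` with resolved
#'   defaults: `threshold`, `profile`, and `static` / `dynamic` blocks
#'   ready for [run_scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_scenario(raw, dir = dirname(path))
}

need_field <- function(block, name, where) {
  if (is.null(block[[name]]))
    stop(sprintf("missing required field '%s' in %s", name, where), call. = FALSE)
  block[[name]]
}

check_fraction <- function(value, name) {
  if (!is.numeric(value) || anyNA(value) || any(value < 0 | value > 1))
    stop(sprintf("field '%s' must be a fraction in [0, 1]", name), call. = FALSE)
  value
}

validate_scenario <- function(raw, dir = ".") {
  if (!is.list(raw)) stop("config must be a mapping/object", call. = FALSE)
  th <- need_field(raw, "threshold", "config")
  threshold <- threshold_policy(need_field(th, "k", "threshold"),
                                th[["currency"]] %||% "EUR")
  profile <- build_profile(need_field(raw, "profile", "config"), dir = dir)
  if (is.null(raw$static) && is.null(raw$dynamic))
    stop("config needs a 'static' and/or 'dynamic' block", call. = FALSE)

  out <- list(threshold = threshold, profile = profile, seed = raw$seed)

  if (!is.null(raw[["static"]])) {
    st <- raw[["static"]]
    p <- check_fraction(need_field(st, "p", "static"), "p")
    sigma <- check_fraction(st[["sigma"]] %||% p, "sigma")
    out$static <- list(n = need_field(st, "n", "static"), p = p, sigma = sigma,
                       strategy_cost = st[["strategy_cost"]] %||% 0)
  }
  if (!is.null(raw[["dynamic"]])) {
    dy <- raw[["dynamic"]]
    horizon <- need_field(dy, "horizon", "dynamic")
    baseline <- if (!is.null(dy[["baseline"]])) {
      check_fraction(dy[["baseline"]], "baseline")
    } else {
      dif <- need_field(dy, "diffusion", "dynamic")
      linear_diffusion(check_fraction(need_field(dif, "start", "diffusion"), "diffusion.start"),
                       need_field(dif, "step", "diffusion"), horizon)
    }
    strategy <- if (!is.null(dy[["strategy"]])) {
      check_fraction(dy[["strategy"]], "strategy")
    } else if (!is.null(dy[["strategy_offset"]])) {
      pmin(1, baseline + dy[["strategy_offset"]])
    }
    convention <- dy[["convention"]] %||% "first_year_undiscounted"
    if (!convention %in% c("first_year_undiscounted", "first_year_discounted"))
      stop("field 'convention' must be first_year_undiscounted or first_year_discounted",
           call. = FALSE)
    out$dynamic <- list(
      schedule = schedule_set(horizon, need_field(dy, "population", "dynamic"),
                              baseline, strategy, dy[["costs"]] %||% 0),
      spec = discount_spec(dy[["rate"]] %||% 0.03, convention))
  }
  structure(out, class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_profile <- function(spec, dir = ".") {
  kind <- need_field(spec, "kind", "profile")
  switch(kind,
    constant = constant_profile(need_field(spec, "delta_qaly", "profile"),
                                need_field(spec, "delta_cost", "profile")),
    linear = linear_profile(need_field(spec, "health_slope", "profile"),
                            need_field(spec, "health_intercept", "profile"),
                            need_field(spec, "cost_slope", "profile"),
                            need_field(spec, "cost_intercept", "profile")),
    tabulated = tabulated_profile(need_field(spec, "p", "profile"),
                                  need_field(spec, "delta_qaly", "profile"),
                                  need_field(spec, "delta_cost", "profile")),
    fit = {
      path <- need_field(spec, "path", "profile")
      if (!file.exists(path)) path <- file.path(dir, path)
      as_linear_profile(nmb_metamodel(read_marginal_triples(path)),
                        rounded = spec[["rounded"]] %||% TRUE)
    },
    stop("unknown profile kind: ", kind, call. = FALSE))
}

#' Run a configured scenario
#'
#' Executes the static and/or dynamic analyses described by a
#' [scenario configuration][load_scenario].
#'
#' @param config a `scenario_config`.
#' @return a list with (when configured) `static` — the one-row summary
#'   from [summary.static_scenario()] — and `dynamic` — a list of
#'   value tables (`current`, and `actual`/`net` when the schedule has
#'   a strategy path).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list()
  if (!is.null(config$static)) {
    s <- static_scenario(config$static$n, config$static$p, config$static$sigma,
                         profile = config$profile, threshold = config$threshold,
                         strategy_cost = config$static$strategy_cost)
    out$static <- summary(s)
  }
  if (!is.null(config$dynamic)) {
    sched <- config$dynamic$schedule
    spec <- config$dynamic$spec
    dyn <- list(current = current_value_stream(sched, config$profile,
                                               config$threshold, spec))
    if (!is.null(sched$strategy)) {
      dyn$actual <- actual_value_stream(sched, config$profile, config$threshold, spec)
      dyn$net <- net_value_stream(sched, config$profile, config$threshold, spec)
    }
    out$dynamic <- dyn
  }
  out
}

#' Write and read value tables
#'
#' `write_value_table()` serialises a [value
#' table][current_value_stream] to CSV (rows of years followed by a
#' final `TOTAL` row) or JSON (rows, totals and discounting metadata);
#' numeric cells are written at full precision, with no currency
#' symbols. `read_value_table()` reads either format back into an
#' equivalent `voimp_value_table`; a write/read round trip reproduces
#' the values to within 1e-9.
#'
#' @param table a `voimp_value_table`.
#' @param path output (input) file path.
#' @param format `"csv"` or `"json"`; `read_value_table()` infers it
#'   from the file extension by default.
#' @return `write_value_table()`: `path`, invisibly.
#' @export
write_value_table <- function(table, path, format = c("csv", "json")) {
  stopifnot(inherits(table, "voimp_value_table"))
  format <- match.arg(format)
  df <- as.data.frame(table)
  totals <- attr(table, "totals")
  if (format == "csv") {
    total_row <- df[NA_integer_, , drop = FALSE][1L, ]
    total_row[] <- NA
    for (nm in names(totals)) total_row[[nm]] <- totals[[nm]]
    out <- cbind(row = c(rep("", nrow(df)), "TOTAL"), rbind(df, total_row))
    utils::write.csv(format(out, digits = 15L, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(list(rows = df, totals = as.list(totals),
                              rate = attr(table, "rate"),
                              convention = attr(table, "convention")),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_value_table
#' @return `read_value_table()`: a `voimp_value_table`.
#' @export
read_value_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    is_total <- raw$row == "TOTAL"
    df <- raw[!is_total, setdiff(names(raw), "row"), drop = FALSE]
    meta <- c("year", "p", "sigma", "discount_factor")
    vcols <- setdiff(names(df), meta)
    totals <- unlist(raw[is_total, vcols, drop = FALSE])
    rate <- NA_real_; convention <- NA_character_
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$rows)
    vcols <- names(obj$totals)
    totals <- unlist(obj$totals)
    rate <- obj$rate; convention <- obj$convention
  }
  rownames(df) <- NULL
  structure(df, class = c("voimp_value_table", "data.frame"),
            value_columns = vcols, totals = stats::setNames(as.numeric(totals), vcols),
            rate = rate, convention = convention)
}
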