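# One-at-a-time (univariate, tornado) sensitivity analysis.
#
# A scenario names one parameter block and how to perturb it in each
# direction: a relative multiplier (the prevalence / incidence scenarios
# use 0.75 and 1.25) or substitution of the stored min/max bounds (unit
# costs use the cost_min / cost_max columns; resource-use blocks their
# qty_min / qty_max columns). Scenarios are pure: they return a modified
# copy and never touch the baseline inputs.

SCENARIO_PARAMS <- c("prevalence", "incidence", "unit_costs",
                     "resource_use.diagnosis", "resource_use.monitoring",
                     "exacerbation", "end_of_life", "exacerbation_rate")

#' Define a univariate sensitivity scenario
#'
#' @param parameter_id one of
#'   `prevalence`, `incidence` (epidemiological estimates),
#'   `unit_costs` (whole catalogue), `resource_use.diagnosis`,
#'   `resource_use.monitoring` (whole resource-use blocks),
#'   `exacerbation`, `end_of_life` (component cost blocks),
#'   `exacerbation_rate` (per-course event rates).
#' @param min_multiplier,max_multiplier strictly positive relative
#'   multipliers for the two directions (e.g. 0.75 / 1.25 for +/-25%).
#' @param bounds if `TRUE`, substitute the stored min/max values instead of
#'   multiplying: `cost_min`/`cost_max` for `unit_costs`,
#'   `qty_min`/`qty_max` for resource-use blocks.
#' @return an `ipf_scenario` object.
#' @export
ipf_scenario <- function(parameter_id, min_multiplier = NULL,
                         max_multiplier = NULL, bounds = FALSE) {
  if (!is.character(parameter_id) || length(parameter_id) != 1L ||
      !parameter_id %in% SCENARIO_PARAMS)
    abort_reference(sprintf(
      "unknown sensitivity parameter '%s' (supported: %s)",
      paste(parameter_id, collapse = ", "),
      paste(SCENARIO_PARAMS, collapse = ", ")))
  if (!bounds) {
    for (m in list(min_multiplier, max_multiplier))
      if (!is_scalar_num(m) || m <= 0)
        abort_validation("multipliers must be single positive numbers",
                         parameter_id)
  }
  structure(list(parameter_id = parameter_id,
                 min_multiplier = min_multiplier,
                 max_multiplier = max_multiplier,
                 bounds = isTRUE(bounds)),
            class = "ipf_scenario")
}

scale_block <- function(df, col, m) { df[[col]] <- df[[col]] * m; df }

substitute_qty <- function(df, col, what) {
  if (!col %in% names(df))
    abort_reference(sprintf(
      "scenario requests stored bounds but column '%s' is absent (%s)",
      col, what))
  df$quantity <- df[[col]]
  df
}

#' Apply one scenario direction to a copy of the inputs
#'
#' @param inputs baseline [ipf_inputs] (never modified).
#' @param s an [ipf_scenario].
#' @param direction `"min"` or `"max"`.
#' @return a modified, re-validated `ipf_inputs` copy in which exactly one
#'   parameter block differs from the baseline.
#' @export
apply_scenario <- function(inputs, s, direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (!inherits(s, "ipf_scenario"))
    abort_validation("'s' must be an ipf_scenario", "scenario")
  x <- inputs
  m <- if (direction == "min") s$min_multiplier else s$max_multiplier
  id <- s$parameter_id

  if (id == "prevalence") {
    x$epidemiology$prevalence_per_100k <-
      x$epidemiology$prevalence_per_100k * m
  } else if (id == "incidence") {
    x$epidemiology$incidence_per_100k <-
      x$epidemiology$incidence_per_100k * m
  } else if (id == "unit_costs") {
    if (s$bounds) {
      x$unit_costs$cost_mean <-
        x$unit_costs[[paste0("cost_", direction)]]
    } else {
      x$unit_costs <- scale_block(x$unit_costs, "cost_mean", m)
      x$unit_costs$cost_min <- pmin(x$unit_costs$cost_min,
                                    x$unit_costs$cost_mean)
      x$unit_costs$cost_max <- pmax(x$unit_costs$cost_max,
                                    x$unit_costs$cost_mean)
    }
  } else if (id == "resource_use.diagnosis") {
    x$diagnosis_use <- if (s$bounds)
      substitute_qty(x$diagnosis_use, paste0("qty_", direction), id)
    else scale_block(x$diagnosis_use, "quantity", m)
  } else if (id == "resource_use.monitoring") {
    x$monitoring_use <- if (s$bounds)
      substitute_qty(x$monitoring_use, paste0("qty_", direction), id)
    else scale_block(x$monitoring_use, "quantity", m)
  } else if (id == "exacerbation") {
    for (f in names(x$exacerbation))
      x$exacerbation[[f]] <- x$exacerbation[[f]] * m
  } else if (id == "end_of_life") {
    for (f in names(x$end_of_life))
      x$end_of_life[[f]] <- x$end_of_life[[f]] * m
  } else if (id == "exacerbation_rate") {
    x$courses <- scale_block(x$courses, "exacerbations_per_year", m)
  }
  suppressWarnings(validate_inputs(x))
  x
}

#' Run a univariate sensitivity analysis
#'
#' For each scenario the weighted TOTAL of the breakdown table is
#' recomputed under the min and the max perturbation; percent differences
#' against the base case are stored unrounded (Table-style integer display
#' happens in [write_results()]).
#'
#' @param inputs baseline [ipf_inputs].
#' @param scenarios list of [ipf_scenario] objects.
#' @return an `ipf_sensitivity` data.frame with columns `parameter_id`,
#'   `cost_at_min`, `cost_at_max`, `pct_diff_min`, `pct_diff_max`; the base
#'   weighted total is kept in the `"base_total"` attribute.
#' @export
run_univariate <- function(inputs, scenarios) {
  base <- build_breakdown_table(inputs)["TOTAL", "weighted"]
  rows <- lapply(scenarios, function(s) {
    lo <- build_breakdown_table(
      apply_scenario(inputs, s, "min"))["TOTAL", "weighted"]
    hi <- build_breakdown_table(
      apply_scenario(inputs, s, "max"))["TOTAL", "weighted"]
    data.frame(parameter_id = s$parameter_id,
               cost_at_min = lo, cost_at_max = hi,
               pct_diff_min = (lo - base) / base * 100,
               pct_diff_max = (hi - base) / base * 100,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter_id = character(), cost_at_min = numeric(),
               cost_at_max = numeric(), pct_diff_min = numeric(),
               pct_diff_max = numeric(), stringsAsFactors = FALSE)
  structure(out, class = c("ipf_sensitivity", "data.frame"),
            base_total = base)
}

#' Order sensitivity results for a tornado diagram
#'
#' Parameters sorted by the larger absolute percent difference,
#' descending; ties broken alphabetically by parameter id.
#'
#' @param results an `ipf_sensitivity` data.frame.
#' @return the same rows in tornado order.
#' @export
tornado_ranking <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L)
    abort_domain("cannot rank an empty sensitivity result set")
  spread <- pmax(abs(results$pct_diff_min), abs(results$pct_diff_max))
  results[order(-spread, results$parameter_id), , drop = FALSE]
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the base-case weighted total to each scenario's min
#' and max totals, in tornado order.
#'
#' @param results an `ipf_sensitivity` data.frame from [run_univariate()].
#' @param ... passed to [graphics::barplot()]-level par settings (unused).
#' @return invisibly, the ranked results.
#' @export
plot_tornado <- function(results, ...) {
  r <- tornado_ranking(results)
  base <- attr(results, "base_total")
  if (is.null(base)) base <- mean(c(r$cost_at_min, r$cost_at_max))
  n <- nrow(r)
  old <- graphics::par(mar = c(5, 14, 2, 2))
  on.exit(graphics::par(old))
  xlim <- range(c(r$cost_at_min, r$cost_at_max, base))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Weighted annual cost per patient (EUR)", ylab = "",
                 main = "Univariate sensitivity")
  for (i in seq_len(n)) {
    y <- n - i + 1
    graphics::rect(min(r$cost_at_min[i], base), y - 0.3,
                   max(r$cost_at_min[i], base), y + 0.3, col = "steelblue")
    graphics::rect(min(r$cost_at_max[i], base), y - 0.3,
                   max(r$cost_at_max[i], base), y + 0.3, col = "firebrick")
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = n:1, labels = r$parameter_id, las = 1,
                 cex.axis = 0.8)
  invisible(r)
}

#' Read a scenario file
#'
#' JSON (or YAML) array of objects with fields `parameter_id` and either
#' `min_multiplier` + `max_multiplier` or `"bounds": true`.
#'
#' @param path scenario file path.
#' @return list of [ipf_scenario] objects.
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("scenario file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_io("YAML input requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  lapply(raw, function(r)
    ipf_scenario(r$parameter_id,
                 min_multiplier = r$min_multiplier,
                 max_multiplier = r$max_multiplier,
                 bounds = isTRUE(r$bounds)))
}
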