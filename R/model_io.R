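# Input data model: construction, validation, reading and writing.
#
# The model tree is held as an `ipf_inputs` list. Tabular blocks are plain
# data.frames; scalar blocks are named lists. On disk the tree is a single
# JSON (or YAML) document; any tabular block may instead be the string
# "csv:<relative path>" pointing at a side-table in the documented CSV
# dialect (UTF-8, comma separator, header row, period decimal separator).

COST_CATEGORIES <- c("diagnosis", "treatment", "monitoring",
                     "exacerbations", "end_of_life")

# components that may be pinned per course by a calibrated override
OVERRIDABLE_COMPONENTS <- setdiff(COST_CATEGORIES, "diagnosis")

#' Assemble a validated cost-model input set
#'
#' Bundles every input of the prevalence-based cost model into one object:
#' epidemiology, disease-course definitions, a unit-cost catalogue,
#' resource-use profiles for diagnosis and monitoring, drug regimens with
#' their adverse-event profiles, non-pharmacological therapies, and the
#' exacerbation and end-of-life cost components.
#'
#' @param epidemiology list with `population` (persons),
#'   `prevalence_per_100k`, `incidence_per_100k` (cases per 100,000) and
#'   `diagnostic_rate` (fraction in \[0,1\]).
#' @param courses data.frame with columns `label`, `proportion` (fractions
#'   summing to 1), `median_survival_months` (> 0) and
#'   `exacerbations_per_year` (events per patient-year).
#' @param unit_costs data.frame with columns `resource_id`, `description`,
#'   `cost_mean`, `cost_min`, `cost_max` (EUR; min <= mean <= max).
#' @param diagnosis_use data.frame of one-off resource use at diagnosis:
#'   `resource_id`, `quantity` (optional `qty_min`, `qty_max` for
#'   sensitivity ranges).
#' @param monitoring_use data.frame of periodic resource use per course:
#'   `course`, `resource_id`, `quantity`, `period_months` (e.g. 3 for a
#'   quarterly profile; optional `qty_min`, `qty_max`).
#' @param drugs data.frame of drug regimens in long form: `drug_id`,
#'   `course`, `pct_patients` (fraction treated), `unit_cost` (EUR/dose
#'   unit), `daily_dose_units`, `duration_days` (days/year, <= 366).
#' @param adverse_events data.frame: `drug_id`, `ae_id`, `grade` (1-4),
#'   `pct_patients` (fraction of treated patients), `cost_nonhospitalized`,
#'   `cost_hospitalized` (EUR/event-patient), `hospitalized_fraction`
#'   (grade-3 hospitalisation split; grade 4 is always hospitalised).
#' @param nonpharma data.frame: `therapy_id`, `course`, `pct_patients`,
#'   `unit_cost` (EUR).
#' @param exacerbation list with `diagnosis_cost`, `treatment_cost`,
#'   `resource_followup_cost` (EUR per event).
#' @param end_of_life list with `treatment_cost` and `visit_cost` (EUR per
#'   patient, lump sums distributed by annual mortality).
#' @param overrides optional data.frame (`course`, `component`, `value`)
#'   pinning a per-course annual component (any of
#'   `r paste(OVERRIDABLE_COMPONENTS, collapse = ", ")`) to a calibrated
#'   value, bypassing the bottom-up computation for that cell.
#' @param metadata optional list of pass-through annotations (not used in
#'   any cost formula).
#' @return an object of class `ipf_inputs`.
#' @seealso [load_inputs()], [validate_inputs()], [build_breakdown_table()]
#' @export
ipf_inputs <- function(epidemiology, courses, unit_costs,
                       diagnosis_use, monitoring_use,
                       drugs = NULL, adverse_events = NULL, nonpharma = NULL,
                       exacerbation = list(diagnosis_cost = 0,
                                           treatment_cost = 0,
                                           resource_followup_cost = 0),
                       end_of_life = list(treatment_cost = 0, visit_cost = 0),
                       overrides = NULL, metadata = list()) {
  x <- structure(list(
    epidemiology   = epidemiology,
    courses        = courses,
    unit_costs     = unit_costs,
    diagnosis_use  = diagnosis_use,
    monitoring_use = monitoring_use,
    drugs          = drugs,
    adverse_events = adverse_events,
    nonpharma      = nonpharma,
    exacerbation   = exacerbation,
    end_of_life    = end_of_life,
    overrides      = overrides,
    metadata       = metadata
  ), class = "ipf_inputs")
  validate_inputs(x)
}

#' Validate a cost-model input set
#'
#' Checks every structural invariant of the input tree and fails with a
#' classed condition: `ipf_validation_error` for a field/constraint
#' violation, `ipf_reference_error` for a dangling `resource_id` or unknown
#' course label. An incidence larger than the prevalence and unit costs
#' never referenced by any resource-use item only raise warnings.
#'
#' @param x an `ipf_inputs` object (or bare list with the same shape).
#' @return `x`, invisibly re-classed as `ipf_inputs`, when valid.
#' @export
validate_inputs <- function(x) {
  if (!is.list(x)) abort_validation("inputs must be a list", "inputs")
  for (f in c("epidemiology", "courses", "unit_costs", "diagnosis_use",
              "monitoring_use", "exacerbation", "end_of_life"))
    if (is.null(x[[f]])) abort_validation(paste0("missing block '", f, "'"), f)

  epi <- x$epidemiology
  if (!is_scalar_num(epi$population) || epi$population <= 0)
    abort_validation("'population' must be > 0", "epidemiology.population")
  if (!is_scalar_num(epi$prevalence_per_100k) || epi$prevalence_per_100k <= 0)
    abort_validation("'prevalence_per_100k' must be > 0",
                     "epidemiology.prevalence_per_100k")
  if (!is_scalar_num(epi$incidence_per_100k) || epi$incidence_per_100k < 0)
    abort_validation("'incidence_per_100k' must be >= 0",
                     "epidemiology.incidence_per_100k")
  check_fraction(epi$diagnostic_rate, "epidemiology.diagnostic_rate")
  if (epi$incidence_per_100k > epi$prevalence_per_100k)
    warning("incidence exceeds prevalence; the diagnosis annualization ",
            "ratio will exceed 1", call. = FALSE)

  cr <- check_cols(x$courses, c("label", "proportion",
                                "median_survival_months",
                                "exacerbations_per_year"), "courses")
  if (nrow(cr) == 0L) abort_validation("course list is empty", "courses")
  if (anyDuplicated(cr$label))
    abort_validation("course labels must be unique", "courses.label")
  if (any(!is.finite(cr$proportion)) || any(cr$proportion < 0) ||
      any(cr$proportion > 1))
    abort_validation("course proportions must lie in [0, 1]",
                     "courses.proportion")
  if (abs(sum(cr$proportion) - 1) > 1e-9)
    abort_validation(sprintf(
      "course proportions must sum to 1 (got %.12g)", sum(cr$proportion)),
      "courses.proportion")
  if (any(!is.finite(cr$median_survival_months)) ||
      any(cr$median_survival_months <= 0))
    abort_validation("median survival must be > 0 months",
                     "courses.median_survival_months")
  check_nonneg(cr$exacerbations_per_year, "courses.exacerbations_per_year")

  uc <- check_cols(x$unit_costs, c("resource_id", "cost_mean",
                                   "cost_min", "cost_max"), "unit_costs")
  if (anyDuplicated(uc$resource_id))
    abort_reference(sprintf(
      "duplicated resource_id in unit_costs: %s",
      paste(unique(uc$resource_id[duplicated(uc$resource_id)]),
            collapse = ", ")))
  check_nonneg(unlist(uc[c("cost_mean", "cost_min", "cost_max")]),
               "unit_costs")
  bad <- uc$cost_min > uc$cost_mean + 1e-9 | uc$cost_mean > uc$cost_max + 1e-9
  if (any(bad))
    abort_validation(sprintf(
      "cost_min <= cost_mean <= cost_max violated for: %s",
      paste(uc$resource_id[bad], collapse = ", ")), "unit_costs")

  du <- check_cols(x$diagnosis_use, c("resource_id", "quantity"),
                   "diagnosis_use")
  check_nonneg(du$quantity, "diagnosis_use.quantity")

  mu <- check_cols(x$monitoring_use,
                   c("course", "resource_id", "quantity", "period_months"),
                   "monitoring_use")
  check_nonneg(mu$quantity, "monitoring_use.quantity")
  if (nrow(mu) && (any(!is.finite(mu$period_months)) ||
                   any(mu$period_months <= 0)))
    abort_validation("'period_months' must be > 0",
                     "monitoring_use.period_months")

  course_set <- cr$label
  check_course <- function(vals, what) {
    unknown <- setdiff(unique(vals), course_set)
    if (length(unknown))
      abort_reference(sprintf("unknown course label(s) in %s: %s", what,
                              paste(unknown, collapse = ", ")))
  }
  check_course(mu$course, "monitoring_use")

  if (!is.null(x$drugs) && nrow(x$drugs)) {
    dr <- check_cols(x$drugs, c("drug_id", "course", "pct_patients",
                                "unit_cost", "daily_dose_units",
                                "duration_days"), "drugs")
    check_course(dr$course, "drugs")
    if (any(dr$pct_patients < 0) || any(dr$pct_patients > 1))
      abort_validation("'pct_patients' must lie in [0, 1]",
                       "drugs.pct_patients")
    if (any(dr$duration_days < 0) || any(dr$duration_days > 366))
      abort_validation("'duration_days' must lie in [0, 366]",
                       "drugs.duration_days")
    check_nonneg(dr$unit_cost, "drugs.unit_cost")
    check_nonneg(dr$daily_dose_units, "drugs.daily_dose_units")
  }

  if (!is.null(x$adverse_events) && nrow(x$adverse_events)) {
    ae <- check_cols(x$adverse_events,
                     c("drug_id", "ae_id", "grade", "pct_patients",
                       "cost_nonhospitalized", "cost_hospitalized",
                       "hospitalized_fraction"), "adverse_events")
    if (!all(ae$grade %in% 1:4))
      abort_validation("'grade' must be an integer in 1..4",
                       "adverse_events.grade")
    if (any(ae$pct_patients < 0) || any(ae$pct_patients > 1) ||
        any(ae$hospitalized_fraction < 0) || any(ae$hospitalized_fraction > 1))
      abort_validation("adverse-event fractions must lie in [0, 1]",
                       "adverse_events")
    check_nonneg(unlist(ae[c("cost_nonhospitalized", "cost_hospitalized")]),
                 "adverse_events")
    if (!is.null(x$drugs)) {
      orphan <- setdiff(unique(ae$drug_id), unique(x$drugs$drug_id))
      if (length(orphan))
        abort_reference(sprintf(
          "adverse events reference unknown drug_id(s): %s",
          paste(orphan, collapse = ", ")))
    }
  }

  if (!is.null(x$nonpharma) && nrow(x$nonpharma)) {
    np <- check_cols(x$nonpharma, c("therapy_id", "course", "pct_patients",
                                    "unit_cost"), "nonpharma")
    check_course(np$course, "nonpharma")
    if (any(np$pct_patients < 0) || any(np$pct_patients > 1))
      abort_validation("'pct_patients' must lie in [0, 1]",
                       "nonpharma.pct_patients")
    check_nonneg(np$unit_cost, "nonpharma.unit_cost")
  }

  for (f in c("diagnosis_cost", "treatment_cost", "resource_followup_cost"))
    check_nonneg(x$exacerbation[[f]], paste0("exacerbation.", f))
  for (f in c("treatment_cost", "visit_cost"))
    check_nonneg(x$end_of_life[[f]], paste0("end_of_life.", f))

  if (!is.null(x$overrides) && nrow(x$overrides)) {
    ov <- check_cols(x$overrides, c("course", "component", "value"),
                     "overrides")
    check_course(ov$course, "overrides")
    bad <- setdiff(unique(ov$component), OVERRIDABLE_COMPONENTS)
    if (length(bad))
      abort_validation(sprintf(
        "overrides allowed only for components %s (got: %s)",
        paste(OVERRIDABLE_COMPONENTS, collapse = ", "),
        paste(bad, collapse = ", ")), "overrides.component")
    if (anyDuplicated(ov[c("course", "component")]))
      abort_validation("duplicate (course, component) override",
                       "overrides")
    check_nonneg(ov$value, "overrides.value")
  }

  # every referenced resource_id must resolve to exactly one catalogue entry
  referenced <- unique(c(du$resource_id, mu$resource_id))
  dangling <- setdiff(referenced, uc$resource_id)
  if (length(dangling))
    abort_reference(sprintf("resource_id(s) with no unit-cost entry: %s",
                            paste(dangling, collapse = ", ")))
  unused <- setdiff(uc$resource_id, referenced)
  if (length(unused))
    warning(sprintf("%d unit-cost entr%s never referenced (%s)",
                    length(unused), if (length(unused) == 1) "y is" else "ies are",
                    paste(utils::head(unused, 5), collapse = ", ")),
            call. = FALSE)

  class(x) <- "ipf_inputs"
  invisible(x)
}

TABULAR_BLOCKS <- c("courses", "unit_costs", "diagnosis_use",
                    "monitoring_use", "drugs", "adverse_events",
                    "nonpharma", "overrides")

#' Read a cost-model input file
#'
#' Reads a JSON (or, when the yaml package is installed, YAML) document
#' holding the full model tree and returns a validated [ipf_inputs] object.
#' A tabular block may be given inline (array of records) or as the string
#' `"csv:<path>"` referencing a CSV file relative to the document.
#'
#' @param path path to a `.json`, `.yaml`/`.yml` input file.
#' @return a validated `ipf_inputs` object.
#' @examples
#' baseline <- load_inputs(system.file("extdata", "baseline.json",
#'                                     package = "ipfcoi"))
#' baseline$epidemiology$prevalence_per_100k
#' @export
load_inputs <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort_io(sprintf("input file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_io("YAML input requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
             error = function(e) abort_io(
               sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  }
  base_dir <- dirname(path)
  for (blk in TABULAR_BLOCKS) {
    v <- raw[[blk]]
    if (is.null(v)) next
    if (is.character(v) && length(v) == 1L && startsWith(v, "csv:")) {
      csv <- file.path(base_dir, sub("^csv:", "", v))
      if (!file.exists(csv)) abort_io(sprintf("CSV side-table not found: %s", csv))
      raw[[blk]] <- utils::read.csv(csv, stringsAsFactors = FALSE,
                                    encoding = "UTF-8")
    } else if (is.list(v) && !is.data.frame(v)) {
      # yaml yields a list of records
      raw[[blk]] <- do.call(rbind, lapply(v, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
  }
  x <- structure(raw[c("epidemiology", TABULAR_BLOCKS[1:2],
                       "diagnosis_use", "monitoring_use", "drugs",
                       "adverse_events", "nonpharma", "exacerbation",
                       "end_of_life", "overrides", "metadata")],
                 class = "ipf_inputs")
  names(x) <- c("epidemiology", "courses", "unit_costs", "diagnosis_use",
                "monitoring_use", "drugs", "adverse_events", "nonpharma",
                "exacerbation", "end_of_life", "overrides", "metadata")
  if (is.null(x$metadata)) x$metadata <- list()
  validate_inputs(x)
  x
}

#' Write a cost-model input set to JSON
#'
#' Inverse of [load_inputs()]: serialises the full model tree to a single
#' JSON document (all tabular blocks inline). Numeric fields survive a
#' round-trip unchanged to within double precision.
#'
#' @param x an `ipf_inputs` object.
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_inputs <- function(x, path) {
  validate_inputs(x)
  out <- unclass(x)
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write result tables to a directory
#'
#' Writes the cost breakdown as `breakdown.csv` (categories as rows, course
#' columns plus `weighted`, EUR rounded half-up to 2 decimals), the
#' sensitivity results (when any) as `sensitivity.csv` in tornado order, and
#' a machine-readable `summary.json` carrying both unrounded and
#' display-rounded headline values.
#'
#' @param table an `ipf_cost_table` from [build_breakdown_table()].
#' @param sens optional `ipf_sensitivity` data.frame from [run_univariate()].
#' @param dir output directory (created if absent).
#' @param inputs optional `ipf_inputs`; when given, prevalent/diagnosed case
#'   counts are added to the summary.
#' @return invisible character vector of the files written.
#' @export
write_results <- function(table, sens = NULL, dir, inputs = NULL) {
  if (!inherits(table, "ipf_cost_table"))
    abort_validation("'table' must be an ipf_cost_table", "table")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_io(sprintf("cannot create output directory: %s", dir))
  written <- character()

  bt <- as.data.frame(round_half_up(unclass(table), 2))
  bt <- cbind(category = rownames(table), bt)
  f <- file.path(dir, "breakdown.csv")
  utils::write.csv(bt, f, row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  if (!is.null(sens) && nrow(as.data.frame(sens))) {
    sd <- tornado_ranking(sens)
    sd$cost_at_min <- round_half_up(sd$cost_at_min, 2)
    sd$cost_at_max <- round_half_up(sd$cost_at_max, 2)
    sd$pct_diff_min_display <- round_half_up(sd$pct_diff_min, 0)
    sd$pct_diff_max_display <- round_half_up(sd$pct_diff_max, 0)
    f <- file.path(dir, "sensitivity.csv")
    utils::write.csv(sd, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }

  weighted <- table[, "weighted"]
  shares <- category_shares(weighted[COST_CATEGORIES])
  summary <- list(
    weighted_total = unname(weighted[["TOTAL"]]),
    weighted_total_display = round_half_up(weighted[["TOTAL"]], 2),
    weighted_components = as.list(weighted[COST_CATEGORIES]),
    category_shares_pct = as.list(shares),
    category_shares_pct_display = as.list(format_shares(shares))
  )
  if (!is.null(inputs)) {
    cc <- case_counts(inputs$epidemiology)
    summary$prevalent_cases <- cc$prevalent_cases
    summary$diagnosed_cases <- cc$diagnosed_cases
  }
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, f)
  invisible(written)
}

#' @export
print.ipf_inputs <- function(x, ...) {
  cat("<ipf_inputs>\n")
  cat(sprintf("  population %s, prevalence %.3g/100k, incidence %.3g/100k, diagnostic rate %.0f%%\n",
              format(x$epidemiology$population, big.mark = ","),
              x$epidemiology$prevalence_per_100k,
              x$epidemiology$incidence_per_100k,
              100 * x$epidemiology$diagnostic_rate))
  cat(sprintf("  courses: %s\n",
              paste(sprintf("%s (%.0f%%)", x$courses$label,
                            100 * x$courses$proportion), collapse = ", ")))
  cat(sprintf("  %d unit costs, %d diagnosis-use items, %d monitoring-use items\n",
              nrow(x$unit_costs), nrow(x$diagnosis_use),
              nrow(x$monitoring_use)))
  if (!is.null(x$overrides) && nrow(x$overrides))
    cat(sprintf("  %d calibrated component overrides\n", nrow(x$overrides)))
  invisible(x)
}
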