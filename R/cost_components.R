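# The five annual per-patient cost components, per disease course.

#' Unit-cost lookup table
#'
#' @param unit_costs unit-cost data.frame (`resource_id`, `cost_*` columns).
#' @param column which cost column to use (`cost_mean` by default; the
#'   sensitivity module substitutes `cost_min` / `cost_max`).
#' @return named numeric vector, EUR per resource unit.
#' @export
unit_cost_lookup <- function(unit_costs, column = "cost_mean") {
  if (!column %in% names(unit_costs))
    abort_reference(sprintf("unit-cost column '%s' not present", column))
  stats::setNames(unit_costs[[column]], unit_costs$resource_id)
}

#' Cost of a block of resource use
#'
#' Sum over items of quantity times unit cost.
#'
#' @param items data.frame with `resource_id` and `quantity`.
#' @param costs named numeric vector from [unit_cost_lookup()].
#' @return total cost in EUR.
#' @export
resource_block_cost <- function(items, costs) {
  if (is.null(items) || nrow(items) == 0L) return(0)
  miss <- setdiff(items$resource_id, names(costs))
  if (length(miss))
    abort_reference(sprintf("no unit cost for resource_id(s): %s",
                            paste(miss, collapse = ", ")))
  sum(items$quantity * costs[items$resource_id])
}

#' Annualized per-patient diagnosis cost
#'
#' The one-off diagnostic work-up cost spread over prevalent patients by
#' the incidence-over-prevalence ratio (the fraction newly diagnosed per
#' year). Identical across disease courses.
#'
#' @param total_diagnosis_cost one-off cost of the diagnostic work-up, EUR.
#' @param ratio [annualization_ratio()] value.
#' @return EUR per patient-year.
#' @export
diagnosis_annual_cost <- function(total_diagnosis_cost, ratio) {
  check_nonneg(ratio, "ratio")
  total_diagnosis_cost * ratio
}

#' Annual drug cost for one regimen row in one course
#'
#' pct of patients treated x unit cost x daily dose x treatment days/year.
#'
#' @param regimen one row of the `drugs` table (list or 1-row data.frame).
#' @return EUR per patient-year (averaged over all patients in the course).
#' @export
drug_annual_cost <- function(regimen) {
  regimen$pct_patients * regimen$unit_cost * regimen$daily_dose_units *
    regimen$duration_days
}

#' Annual cost of drug-related adverse events
#'
#' Applies the inclusion rules: only grade >= 3 events affecting strictly
#' more than `threshold` (default 5%) of treated patients carry a cost.
#' Grade-3 events split between hospitalised and non-hospitalised
#' management by `hospitalized_fraction`; grade-4 events are always
#' hospitalised.
#'
#' @param aes adverse-event data.frame rows for one drug.
#' @param pct_on_drug fraction of the course's patients on the drug.
#' @param threshold strict inclusion threshold on `pct_patients`
#'   (default 0.05; an event at exactly the threshold is excluded).
#' @return EUR per patient-year.
#' @export
adverse_event_annual_cost <- function(aes, pct_on_drug, threshold = 0.05) {
  if (is.null(aes) || nrow(aes) == 0L) return(0)
  check_fraction(pct_on_drug, "pct_on_drug")
  keep <- aes$grade >= 3 & aes$pct_patients > threshold
  if (!any(keep)) return(0)
  aes <- aes[keep, , drop = FALSE]
  per_event <- ifelse(
    aes$grade >= 4,
    aes$cost_hospitalized,
    aes$hospitalized_fraction * aes$cost_hospitalized +
      (1 - aes$hospitalized_fraction) * aes$cost_nonhospitalized)
  sum(pct_on_drug * aes$pct_patients * per_event)
}

#' Annual cost of non-pharmacological therapies in one course
#'
#' @param therapies `nonpharma` data.frame rows for one course.
#' @return EUR per patient-year (sum of pct of patients x unit cost).
#' @export
nonpharma_annual_cost <- function(therapies) {
  if (is.null(therapies) || nrow(therapies) == 0L) return(0)
  sum(therapies$pct_patients * therapies$unit_cost)
}

#' Annual treatment cost for one course
#'
#' Drugs plus their qualifying adverse events plus non-pharmacological
#' therapies.
#'
#' @param inputs an [ipf_inputs] object.
#' @param course course label.
#' @param costs optional unit-cost lookup (unused by drugs, which carry
#'   their own prices; reserved for future resource-based AE costing).
#' @param ae_threshold adverse-event inclusion threshold, see
#'   [adverse_event_annual_cost()].
#' @return EUR per patient-year.
#' @export
treatment_annual_cost <- function(inputs, course, costs = NULL,
                                  ae_threshold = 0.05) {
  total <- 0
  dr <- inputs$drugs
  if (!is.null(dr) && nrow(dr)) {
    rows <- dr[dr$course == course, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      total <- total + drug_annual_cost(r)
      ae <- inputs$adverse_events
      if (!is.null(ae) && nrow(ae)) {
        ae_rows <- ae[ae$drug_id == r$drug_id, , drop = FALSE]
        total <- total + adverse_event_annual_cost(ae_rows, r$pct_patients,
                                                   ae_threshold)
      }
    }
  }
  np <- inputs$nonpharma
  if (!is.null(np) && nrow(np))
    total <- total + nonpharma_annual_cost(np[np$course == course, ,
                                              drop = FALSE])
  total
}

#' Annual monitoring cost for one course
#'
#' Each periodic resource-use item is annualized by 12 / period_months
#' (a quarterly profile therefore counts four times a year) and priced at
#' its unit cost.
#'
#' @param quarterly_use monitoring-use data.frame rows for one course
#'   (`resource_id`, `quantity`, `period_months`).
#' @param costs named unit-cost lookup.
#' @return EUR per patient-year.
#' @export
monitoring_annual_cost <- function(quarterly_use, costs) {
  if (is.null(quarterly_use) || nrow(quarterly_use) == 0L) return(0)
  miss <- setdiff(quarterly_use$resource_id, names(costs))
  if (length(miss))
    abort_reference(sprintf("no unit cost for resource_id(s): %s",
                            paste(miss, collapse = ", ")))
  sum(quarterly_use$quantity * costs[quarterly_use$resource_id] *
        12 / quarterly_use$period_months)
}

#' Cost of one acute exacerbation event
#'
#' Diagnosis plus treatment plus healthcare resource use and follow-up.
#'
#' @param c exacerbation component list (`diagnosis_cost`,
#'   `treatment_cost`, `resource_followup_cost`).
#' @return EUR per event.
#' @export
exacerbation_event_cost <- function(c) {
  c$diagnosis_cost + c$treatment_cost + c$resource_followup_cost
}

#' Annual exacerbation cost for one course
#'
#' @param event_cost EUR per exacerbation event.
#' @param rate exacerbations per patient-year for the course.
#' @return EUR per patient-year.
#' @export
exacerbation_annual_cost <- function(event_cost, rate) {
  check_nonneg(rate, "rate")
  event_cost * rate
}

#' Lump end-of-life care cost per patient
#'
#' @param c end-of-life component list (`treatment_cost`, `visit_cost`).
#' @return EUR per patient (not yet distributed over years).
#' @export
eol_lump_cost <- function(c) {
  c$treatment_cost + c$visit_cost
}

#' Annualized end-of-life cost for one course
#'
#' The lump end-of-life cost multiplied by the course's annual mortality
#' rate: only the fraction of patients dying in a given year incurs it.
#'
#' @param lump EUR per dying patient, from [eol_lump_cost()].
#' @param annual_mortality fraction in \[0, 1\], from
#'   [deale_annual_mortality()].
#' @return EUR per patient-year.
#' @export
eol_annual_cost <- function(lump, annual_mortality) {
  check_fraction(annual_mortality, "annual_mortality")
  lump * annual_mortality
}

#' The five annual cost components for one disease course
#'
#' Assembles diagnosis, treatment, monitoring, exacerbation and end-of-life
#' components for one course. Components pinned by a calibrated override in
#' `inputs$overrides` take that value; all others are computed bottom-up
#' from resource use, unit costs, regimens and rates. The diagnosis
#' component is identical across courses by construction.
#'
#' @param inputs an [ipf_inputs] object.
#' @param course course label.
#' @param ae_threshold adverse-event inclusion threshold.
#' @return named numeric vector over
#'   `diagnosis, treatment, monitoring, exacerbations, end_of_life`
#'   (EUR per patient-year), with the course label as attribute.
#' @export
course_cost_vector <- function(inputs, course, ae_threshold = 0.05) {
  cr <- inputs$courses
  if (!course %in% cr$label)
    abort_reference(sprintf("unknown course label: %s", course))
  row <- cr[cr$label == course, ]
  costs <- unit_cost_lookup(inputs$unit_costs)

  ratio <- annualization_ratio(inputs$epidemiology$incidence_per_100k,
                               inputs$epidemiology$prevalence_per_100k)
  v <- c(
    diagnosis = diagnosis_annual_cost(
      resource_block_cost(inputs$diagnosis_use, costs), ratio),
    treatment = treatment_annual_cost(inputs, course,
                                      ae_threshold = ae_threshold),
    monitoring = monitoring_annual_cost(
      inputs$monitoring_use[inputs$monitoring_use$course == course, ,
                            drop = FALSE], costs),
    exacerbations = exacerbation_annual_cost(
      exacerbation_event_cost(inputs$exacerbation),
      row$exacerbations_per_year),
    end_of_life = eol_annual_cost(
      eol_lump_cost(inputs$end_of_life),
      deale_annual_mortality(row$median_survival_months))
  )

  ov <- inputs$overrides
  if (!is.null(ov) && nrow(ov)) {
    ov <- ov[ov$course == course, , drop = FALSE]
    v[ov$component] <- ov$value
  }
  attr(v, "course") <- course
  v
}
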