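# Baseline Spanish IPF input set.
#
# Epidemiology, disease-course mix, survivals, exacerbation rates, the
# exacerbation and end-of-life cost components, drug shares and the
# adverse-event grade/percent profile are the published consensus-panel
# estimates. Unit costs for visits/tests and drug doses/durations were
# published only in supplementary material, so this fixture carries
# SYNTHETIC placeholder prices (plausible 2013 Spanish tariffs), with the
# diagnostic work-up calibrated so its one-off total matches the published
# EUR 4,736.28. The per-course treatment, monitoring and exacerbation
# components are pinned by calibrated overrides to the published annual
# values; diagnosis and end-of-life are computed through the
# annualization-ratio and DEALE chains.

#' Baseline model inputs (Spanish IPF cost model)
#'
#' The calibrated base-case input set: prevalence 12 and incidence 3 per
#' 100,000, population 46,039,979, diagnostic rate 85%; courses stable /
#' slow / rapid at 20/60/20% with median survivals 66/42/15 months and
#' 0.76/0.82/1.8 exacerbations per patient-year; exacerbation event
#' components EUR 339 + 305 + 11,074; end-of-life components EUR 463 +
#' 864. Treatment, monitoring and exacerbation per-course annual costs are
#' supplied as calibrated overrides (their underlying unit costs are not
#' public); unit costs in the catalogue are synthetic placeholders, with
#' the diagnosis block calibrated to a EUR 4,736.28 one-off total.
#'
#' @return a validated [ipf_inputs] object.
#' @examples
#' b <- baseline_inputs()
#' round_half_up(build_breakdown_table(b)["TOTAL", "weighted"])  # 26435
#' @export
baseline_inputs <- function() {
  unit_costs <- data.frame(
    resource_id = c("gp_visit", "pulmonology_visit", "lab_panel",
                    "chest_xray", "hrct", "bronchoscopy_bal_tbb",
                    "surgical_lung_biopsy", "blood_gases", "rft_full",
                    "er_visit", "pulm_ward_day", "icu_day", "cbc", "esr",
                    "liver_profile", "cpk", "spirometry",
                    "plethysmography", "dlco", "walk_test_6min"),
    description = c("Primary care visit", "Pulmonology visit",
                    "Laboratory panel", "Chest X-ray",
                    "High-resolution CT",
                    "Bronchoscopy with BAL and transbronchial biopsy",
                    "Surgical lung biopsy", "Arterial blood gases",
                    "Full respiratory function testing",
                    "Emergency room visit", "Pulmonology ward day",
                    "Intensive care unit day", "Complete blood count",
                    "Erythrocyte sedimentation rate", "Liver profile",
                    "Creatine phosphokinase", "Spirometry",
                    "Body plethysmography", "CO diffusing capacity",
                    "6-minute walk test"),
    cost_mean = c(23.19, 58, 30, 23, 135, 450, 3500, 30, 347.90,
                  120, 450, 1200, 3.5, 2.5, 10, 4, 38, 75, 80, 60),
    stringsAsFactors = FALSE)
  unit_costs$cost_min <- round(unit_costs$cost_mean * 0.75, 2)
  unit_costs$cost_max <- round(unit_costs$cost_mean * 1.35, 2)

  # one-off diagnostic work-up; quantities are panel medians, block total
  # calibrated to EUR 4,736.28
  diagnosis_use <- data.frame(
    resource_id = c("gp_visit", "pulmonology_visit", "lab_panel",
                    "chest_xray", "hrct", "bronchoscopy_bal_tbb",
                    "surgical_lung_biopsy", "blood_gases", "rft_full"),
    quantity = c(2, 3, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  diagnosis_use$qty_min <- diagnosis_use$quantity * 0.5
  diagnosis_use$qty_max <- diagnosis_use$quantity * 2

  # quarterly monitoring profiles per course (3-month panel medians)
  mk <- function(course, ids, qty)
    data.frame(course = course, resource_id = ids, quantity = qty,
               period_months = 3, stringsAsFactors = FALSE)
  monitoring_use <- rbind(
    mk("stable", c("pulmonology_visit", "cbc", "spirometry"), c(1, 1, 1)),
    mk("slow",
       c("pulmonology_visit", "cbc", "esr", "liver_profile", "spirometry",
         "plethysmography", "dlco", "walk_test_6min", "chest_xray",
         "blood_gases"),
       c(1, 1, 1, 1, 1, 1, 1, 1, 0.5, 0.3)),
    mk("rapid",
       c("pulmonology_visit", "er_visit", "pulm_ward_day", "icu_day",
         "cbc", "esr", "liver_profile", "cpk", "spirometry",
         "plethysmography", "dlco", "walk_test_6min", "chest_xray",
         "hrct", "blood_gases"),
       c(2, 1, 7.5, 0.8, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1.5)))
  monitoring_use$qty_min <- monitoring_use$quantity * 0.5
  monitoring_use$qty_max <- monitoring_use$quantity * 2

  # drug shares per course are panel estimates; prices/doses are synthetic
  drug <- function(id, pct, cost, dose, days)
    data.frame(drug_id = id, course = c("stable", "slow", "rapid"),
               pct_patients = pct, unit_cost = cost,
               daily_dose_units = dose, duration_days = days,
               stringsAsFactors = FALSE)
  drugs <- rbind(
    drug("nac",            c(0.80, 1.00, 1.00), 0.25, 3.0, 365),
    drug("anticoagulants", c(0.00, 0.00, 0.043), 1.20, 1.0, 365),
    drug("prednisone",     c(0.00, 0.00, 0.50), 0.08, 1.5, 365),
    drug("ltot",           c(0.25, 0.30, 1.00), 3.00, 1.0, 365),
    drug("omeprazole",     c(0.07, 0.07, 0.07), 0.10, 1.0, 365),
    drug("pirfenidone",    c(0.00, 0.05, 0.00), 25.0, 9.0, 365))

  ae <- function(drug_id, ae_id, grade, pct, nonhosp, hosp)
    data.frame(drug_id = drug_id, ae_id = ae_id, grade = grade,
               pct_patients = pct, cost_nonhospitalized = nonhosp,
               cost_hospitalized = hosp, hospitalized_fraction = 0,
               stringsAsFactors = FALSE)
  adverse_events <- rbind(
    # mucolytic: grade 1-2 only, never costed
    ae("nac", "epigastric_pain", 1, 0.05, 0, 0),
    ae("nac", "digestive_intolerance", 1, 0.08, 0, 0),
    ae("nac", "dyspepsia", 1, 0.05, 0, 0),
    ae("anticoagulants", "haematoma", 1, 0.10, 0, 0),
    # systemic corticosteroids (published grade profile; event-management
    # costs published for most events, synthetic where not)
    ae("prednisone", "osteoporosis", 3, 0.18, 89.43, 3495.47),
    ae("prednisone", "osteoporosis", 4, 0.05, 0, 3495.47),
    ae("prednisone", "opportunistic_infections", 3, 0.05, 74.66, 7085.52),
    ae("prednisone", "opportunistic_infections", 4, 0.01, 0, 7085.52),
    ae("prednisone", "oedema", 3, 0.03, 70, 2500),
    ae("prednisone", "myopathy", 3, 0.05, 74.66, 3000),
    ae("prednisone", "myopathy", 4, 0.05, 0, 3000),
    ae("prednisone", "hyperglycaemia", 3, 0.18, 69.93, 3898.39),
    ae("prednisone", "hyperglycaemia", 4, 0.05, 0, 3898.39),
    ae("prednisone", "cushing_syndrome", 3, 0.10, 74.66, 4468.42),
    ae("prednisone", "cushing_syndrome", 4, 0.05, 0, 4468.42),
    ae("prednisone", "compression_fractures", 3, 0.10, 74.66, 3495.47),
    ae("prednisone", "compression_fractures", 4, 0.03, 0, 3495.47),
    ae("prednisone", "diabetes", 3, 0.10, 84.74, 3898.39),
    ae("prednisone", "diabetes", 4, 0.05, 0, 3898.39),
    ae("prednisone", "hypertension", 3, 0.05, 70, 2500),
    ae("prednisone", "cataracts", 3, 0.05, 70, 2500),
    ae("prednisone", "cataracts", 4, 0.01, 0, 2500),
    ae("prednisone", "digestive_intolerance", 3, 0.07, 68.14, 2452.50),
    ae("prednisone", "digestive_intolerance", 4, 0.03, 0, 2452.50),
    # pirfenidone
    ae("pirfenidone", "epigastric_pain", 3, 0.03, 68.14, 2452.50),
    ae("pirfenidone", "nausea", 3, 0.10, 68.14, 3082.73),
    ae("pirfenidone", "asthenia", 3, 0.03, 70, 3082.73),
    ae("pirfenidone", "digestive_intolerance", 3, 0.08, 68.14, 2452.50),
    # long-term oxygen therapy
    ae("ltot", "nasal_dryness", 3, 0.10, 27.95, 1678.20),
    ae("ltot", "nasal_dryness", 4, 0.03, 0, 1678.20),
    ae("ltot", "dry_mouth", 3, 0.03, 27.95, 1678.20))

  nonpharma <- data.frame(
    therapy_id = rep(c("lung_transplant", "pulmonary_rehab"), each = 3),
    course = rep(c("stable", "slow", "rapid"), 2),
    pct_patients = c(0, 0.05, 0.08, 0.10, 0.10, 0.10),
    unit_cost = c(rep(1e5, 3), rep(1800, 3)),
    stringsAsFactors = FALSE)

  # published per-course annual values for components whose underlying
  # doses / unit costs are not public
  overrides <- data.frame(
    course = rep(c("stable", "slow", "rapid"), 3),
    component = rep(c("treatment", "monitoring", "exacerbations"), each = 3),
    value = c(722.26, 8069.33, 10802.52,
              453.94, 1698.91, 24199.00,
              8882.22, 9646.21, 20511.50),
    stringsAsFactors = FALSE)

  suppressWarnings(ipf_inputs(
    epidemiology = list(population = 46039979, prevalence_per_100k = 12,
                        incidence_per_100k = 3, diagnostic_rate = 0.85),
    courses = data.frame(
      label = c("stable", "slow", "rapid"),
      proportion = c(0.2, 0.6, 0.2),
      median_survival_months = c(66, 42, 15),
      exacerbations_per_year = c(0.76, 0.82, 1.8),
      stringsAsFactors = FALSE),
    unit_costs = unit_costs,
    diagnosis_use = diagnosis_use,
    monitoring_use = monitoring_use,
    drugs = drugs,
    adverse_events = adverse_events,
    nonpharma = nonpharma,
    exacerbation = list(diagnosis_cost = 339, treatment_cost = 305,
                        resource_followup_cost = 11074),
    end_of_life = list(treatment_cost = 463, visit_cost = 864),
    overrides = overrides,
    metadata = list(
      currency_year = 2013,
      # descriptive pass-through only; enters no cost formula
      exacerbation_mortality = list(pct_die = 0.51,
                                    pct_die_in_hospital = 0.69,
                                    pct_die_after_discharge = 0.31),
      unit_costs_note = "synthetic placeholder tariffs; diagnosis block calibrated to a 4736.28 EUR one-off total")
  ))
}

#' The published +/-25% prevalence and incidence scenarios
#'
#' @return list of two [ipf_scenario]s (prevalence, incidence), each with
#'   multipliers 0.75 / 1.25.
#' @export
baseline_scenarios <- function() {
  list(ipf_scenario("prevalence", 0.75, 1.25),
       ipf_scenario("incidence", 0.75, 1.25))
}
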