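# Random small fixtures and the flat-enumeration oracle used by the
# property-style tests. The oracle deliberately avoids every package
# costing function: it expands all inputs into flat (fraction, quantity,
# unit-cost, multiplier) records with plain loops and sums them.

random_inputs <- function(seed, n_courses = sample(2:4, 1)) {
  set.seed(seed)
  n_courses <- max(2, n_courses)
  labels <- paste0("course", seq_len(n_courses))
  p <- runif(n_courses, 0.2, 1)
  p <- p / sum(p)

  n_res <- sample(5:8, 1)
  rid <- paste0("res", seq_len(n_res))
  mean_cost <- round(runif(n_res, 10, 500), 2)
  unit_costs <- data.frame(
    resource_id = rid, description = rid,
    cost_mean = mean_cost,
    cost_min = round(mean_cost * runif(n_res, 0.5, 0.9), 2),
    cost_max = round(mean_cost * runif(n_res, 1.1, 1.8), 2),
    stringsAsFactors = FALSE)

  d_ids <- sample(rid, sample(2:n_res, 1))
  diagnosis_use <- data.frame(
    resource_id = d_ids,
    quantity = round(runif(length(d_ids), 0, 4), 1),
    stringsAsFactors = FALSE)
  diagnosis_use$qty_min <- diagnosis_use$quantity * 0.5
  diagnosis_use$qty_max <- diagnosis_use$quantity * 2

  monitoring_use <- do.call(rbind, lapply(labels, function(l) {
    ids <- sample(rid, sample(1:n_res, 1))
    data.frame(course = l, resource_id = ids,
               quantity = round(runif(length(ids), 0, 3), 1),
               period_months = sample(c(1, 3, 6), length(ids),
                                      replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  monitoring_use$qty_min <- monitoring_use$quantity * 0.5
  monitoring_use$qty_max <- monitoring_use$quantity * 2

  n_drugs <- sample(1:3, 1)
  drugs <- do.call(rbind, lapply(seq_len(n_drugs), function(i)
    data.frame(drug_id = paste0("drug", i), course = labels,
               pct_patients = round(runif(n_courses), 2),
               unit_cost = round(runif(1, 0.05, 30), 2),
               daily_dose_units = sample(1:4, 1),
               duration_days = sample(c(30, 180, 365), 1),
               stringsAsFactors = FALSE)))

  n_ae <- sample(0:6, 1)
  adverse_events <- if (n_ae > 0) data.frame(
    drug_id = paste0("drug", sample(n_drugs, n_ae, replace = TRUE)),
    ae_id = paste0("ae", seq_len(n_ae)),
    grade = sample(1:4, n_ae, replace = TRUE),
    pct_patients = round(runif(n_ae, 0, 0.3), 3),
    cost_nonhospitalized = round(runif(n_ae, 20, 150), 2),
    cost_hospitalized = round(runif(n_ae, 1000, 8000), 2),
    hospitalized_fraction = round(runif(n_ae), 2),
    stringsAsFactors = FALSE) else NULL

  nonpharma <- data.frame(
    therapy_id = rep("therapy1", n_courses), course = labels,
    pct_patients = round(runif(n_courses, 0, 0.2), 2),
    unit_cost = round(runif(1, 1000, 90000), 2),
    stringsAsFactors = FALSE)

  # keep fixtures warning-free: reference every catalogue entry and keep
  # incidence below prevalence
  used <- unique(c(diagnosis_use$resource_id, monitoring_use$resource_id))
  unit_costs <- unit_costs[unit_costs$resource_id %in% used, , drop = FALSE]
  prev <- round(runif(1, 2, 40), 1)

  ipf_inputs(
    epidemiology = list(population = round(runif(1, 1e6, 5e7)),
                        prevalence_per_100k = prev,
                        incidence_per_100k = round(prev * runif(1, 0.05, 0.8), 2),
                        diagnostic_rate = round(runif(1, 0.5, 1), 2)),
    courses = data.frame(label = labels, proportion = p,
                         median_survival_months = round(runif(n_courses, 8, 90)),
                         exacerbations_per_year = round(runif(n_courses, 0, 2), 2),
                         stringsAsFactors = FALSE),
    unit_costs = unit_costs, diagnosis_use = diagnosis_use,
    monitoring_use = monitoring_use, drugs = drugs,
    adverse_events = adverse_events, nonpharma = nonpharma,
    exacerbation = list(diagnosis_cost = round(runif(1, 100, 600), 2),
                        treatment_cost = round(runif(1, 100, 600), 2),
                        resource_followup_cost = round(runif(1, 2000, 15000), 2)),
    end_of_life = list(treatment_cost = round(runif(1, 100, 900), 2),
                       visit_cost = round(runif(1, 100, 900), 2))
  )
}

# flat-enumeration oracle: one component vector for one course
oracle_course_costs <- function(x, course, ae_threshold = 0.05) {
  price <- function(id) x$unit_costs$cost_mean[x$unit_costs$resource_id == id]

  diag_total <- 0
  for (i in seq_len(nrow(x$diagnosis_use)))
    diag_total <- diag_total +
      x$diagnosis_use$quantity[i] * price(x$diagnosis_use$resource_id[i])
  diagnosis <- diag_total * x$epidemiology$incidence_per_100k /
    x$epidemiology$prevalence_per_100k

  treatment <- 0
  if (!is.null(x$drugs)) for (i in seq_len(nrow(x$drugs))) {
    r <- x$drugs[i, ]
    if (r$course != course) next
    treatment <- treatment +
      r$pct_patients * r$unit_cost * r$daily_dose_units * r$duration_days
    if (!is.null(x$adverse_events))
      for (j in seq_len(nrow(x$adverse_events))) {
        a <- x$adverse_events[j, ]
        if (a$drug_id != r$drug_id) next
        if (a$grade < 3 || a$pct_patients <= ae_threshold) next
        per_event <- if (a$grade >= 4) a$cost_hospitalized else
          a$hospitalized_fraction * a$cost_hospitalized +
          (1 - a$hospitalized_fraction) * a$cost_nonhospitalized
        treatment <- treatment + r$pct_patients * a$pct_patients * per_event
      }
  }
  if (!is.null(x$nonpharma)) for (i in seq_len(nrow(x$nonpharma))) {
    r <- x$nonpharma[i, ]
    if (r$course == course)
      treatment <- treatment + r$pct_patients * r$unit_cost
  }

  monitoring <- 0
  for (i in seq_len(nrow(x$monitoring_use))) {
    r <- x$monitoring_use[i, ]
    if (r$course == course)
      monitoring <- monitoring +
        r$quantity * price(r$resource_id) * 12 / r$period_months
  }

  cr <- x$courses[x$courses$label == course, ]
  event <- x$exacerbation$diagnosis_cost + x$exacerbation$treatment_cost +
    x$exacerbation$resource_followup_cost
  exac <- event * cr$exacerbations_per_year

  mortality <- min(12 / cr$median_survival_months, 1)
  eol <- (x$end_of_life$treatment_cost + x$end_of_life$visit_cost) * mortality

  c(diagnosis = diagnosis, treatment = treatment, monitoring = monitoring,
    exacerbations = exac, end_of_life = eol)
}

baseline_fixture_path <- function()
  system.file("extdata", "baseline.json", package = "ipfcoi")
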