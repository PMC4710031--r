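test_that("resource_block_cost sums quantity times unit cost", {
  costs <- c(a = 50, b = 300, c = 80, d = 100)
  expect_equal(resource_block_cost(data.frame(resource_id = character(),
                                              quantity = numeric()),
                                   costs), 0)
  expect_equal(resource_block_cost(
    data.frame(resource_id = "d", quantity = 2), costs), 200)
  # hand-enumerated: 2 x 50 + 1 x 300 + 0.5 x 80 = 440
  expect_equal(resource_block_cost(
    data.frame(resource_id = c("a", "b", "c"), quantity = c(2, 1, 0.5)),
    costs), 440)
  expect_error(resource_block_cost(
    data.frame(resource_id = "zz", quantity = 1), costs),
    class = "ipf_reference_error")
})

test_that("diagnosis annualization reproduces the published per-year cost", {
  expect_equal(diagnosis_annual_cost(4736, 0.25), 1184)
  expect_equal(diagnosis_annual_cost(4736.28, 0.25), 1184.07)
  expect_equal(diagnosis_annual_cost(123, 1), 123)
  expect_equal(diagnosis_annual_cost(123, 0), 0)
})

test_that("drug_annual_cost multiplies share, price, dose and duration", {
  expect_equal(drug_annual_cost(list(pct_patients = 0, unit_cost = 9,
                                     daily_dose_units = 2,
                                     duration_days = 365)), 0)
  expect_equal(drug_annual_cost(list(pct_patients = 1, unit_cost = 1,
                                     daily_dose_units = 3,
                                     duration_days = 365)), 1095)
  expect_equal(drug_annual_cost(list(pct_patients = 0.5, unit_cost = 0.10,
                                     daily_dose_units = 2,
                                     duration_days = 300)), 30)
})

test_that("adverse-event costing applies grade and >5% inclusion rules", {
  # grade 1-2 only: excluded regardless of frequency
  mild <- data.frame(drug_id = "d", ae_id = c("pain", "intolerance"),
                     grade = c(1, 2), pct_patients = c(0.5, 0.8),
                     cost_nonhospitalized = 100, cost_hospitalized = 1000,
                     hospitalized_fraction = 0)
  expect_equal(adverse_event_annual_cost(mild, 1), 0)

  # exactly at the 5% threshold: strictly excluded
  at5 <- data.frame(drug_id = "d", ae_id = "x", grade = 3,
                    pct_patients = 0.05, cost_nonhospitalized = 100,
                    cost_hospitalized = 1000, hospitalized_fraction = 0)
  expect_equal(adverse_event_annual_cost(at5, 1), 0)
  # a configurable threshold can re-admit it
  expect_equal(adverse_event_annual_cost(at5, 1, threshold = 0.049),
               0.05 * 100)

  # grade-3 osteoporosis at 18%, non-hospitalised management
  osteo <- data.frame(drug_id = "d", ae_id = "osteoporosis", grade = 3,
                      pct_patients = 0.18, cost_nonhospitalized = 89.43,
                      cost_hospitalized = 3495.47,
                      hospitalized_fraction = 0)
  expect_equal(adverse_event_annual_cost(osteo, 1), 0.18 * 89.43)

  # grade 4 is always hospitalised; grade 3 splits by the fraction
  mix <- data.frame(drug_id = "d", ae_id = c("a", "b"), grade = c(3, 4),
                    pct_patients = c(0.2, 0.1),
                    cost_nonhospitalized = c(80, 0),
                    cost_hospitalized = c(2000, 3000),
                    hospitalized_fraction = c(0.25, 0))
  expect_equal(adverse_event_annual_cost(mix, 0.5),
               0.5 * (0.2 * (0.25 * 2000 + 0.75 * 80) + 0.1 * 3000))
})

test_that("lowering frequency or grade never increases the AE cost", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:5, 1)
    aes <- data.frame(drug_id = "d", ae_id = paste0("e", 1:n),
                      grade = sample(1:4, n, replace = TRUE),
                      pct_patients = runif(n, 0, 0.4),
                      cost_nonhospitalized = runif(n, 10, 200),
                      cost_hospitalized = runif(n, 500, 9000),
                      hospitalized_fraction = runif(n))
    base <- adverse_event_annual_cost(aes, 1)
    i <- sample(n, 1)
    lowered <- aes; lowered$pct_patients[i] <- 0.05
    expect_lte(adverse_event_annual_cost(lowered, 1), base)
    degraded <- aes; degraded$grade[i] <- sample(1:2, 1)
    expect_lte(adverse_event_annual_cost(degraded, 1), base)
  }
})

test_that("nonpharma cost is share times unit cost", {
  expect_equal(nonpharma_annual_cost(NULL), 0)
  expect_equal(nonpharma_annual_cost(
    data.frame(therapy_id = "tx", course = "stable", pct_patients = 0,
               unit_cost = 1e5)), 0)
  expect_equal(nonpharma_annual_cost(
    data.frame(therapy_id = "tx", course = "rapid", pct_patients = 0.08,
               unit_cost = 1e5)), 8000)
})

test_that("monitoring annualizes a quarterly profile by four", {
  costs <- c(visit = 100, labx = 25)
  zeroes <- data.frame(course = "stable", resource_id = "visit",
                       quantity = 0, period_months = 3)
  expect_equal(monitoring_annual_cost(zeroes, costs), 0)
  one_visit <- data.frame(course = "stable", resource_id = "visit",
                          quantity = 1, period_months = 3)
  expect_equal(monitoring_annual_cost(one_visit, costs), 400)
  # mixed periods annualize per item
  mixed <- data.frame(course = "x", resource_id = c("visit", "labx"),
                      quantity = c(2, 3), period_months = c(3, 6))
  expect_equal(monitoring_annual_cost(mixed, costs),
               2 * 100 * 4 + 3 * 25 * 2)
})

test_that("exacerbation event and annual costs reproduce published values", {
  expect_equal(exacerbation_event_cost(list(
    diagnosis_cost = 339, treatment_cost = 305,
    resource_followup_cost = 11074)), 11718)
  expect_equal(exacerbation_event_cost(list(
    diagnosis_cost = 1, treatment_cost = 2,
    resource_followup_cost = 3)), 6)
  expect_equal(exacerbation_annual_cost(11718, 0), 0)
  expect_equal(exacerbation_annual_cost(11718, 1), 11718)
  expect_equal(exacerbation_annual_cost(11718, 0.76), 8905.68)
})

test_that("end-of-life lump and annualized costs follow the DEALE weight", {
  expect_equal(eol_lump_cost(list(treatment_cost = 463, visit_cost = 864)),
               1327)
  expect_equal(eol_annual_cost(1327, 1), 1327)
  expect_equal(eol_annual_cost(1327, 0), 0)
  # published table prints 1,061.62 from its own unrounded lump sum
  expect_equal(eol_annual_cost(1327, 0.80), 1061.62, tolerance = 0.05)
})

test_that("course_cost_vector handles degenerate fixtures", {
  x <- random_inputs(101)
  zero <- x
  zero$unit_costs$cost_mean[] <- 0
  zero$unit_costs$cost_min[] <- 0
  zero$drugs$unit_cost[] <- 0
  if (!is.null(zero$adverse_events)) {
    zero$adverse_events$cost_nonhospitalized[] <- 0
    zero$adverse_events$cost_hospitalized[] <- 0
  }
  zero$nonpharma$unit_cost[] <- 0
  zero$exacerbation <- list(diagnosis_cost = 0, treatment_cost = 0,
                            resource_followup_cost = 0)
  zero$end_of_life <- list(treatment_cost = 0, visit_cost = 0)
  v <- course_cost_vector(zero, zero$courses$label[1])
  expect_equal(unname(v[names(v)]), rep(0, 5))

  only_diag <- zero
  only_diag$unit_costs$cost_mean <- x$unit_costs$cost_mean
  only_diag$monitoring_use <- only_diag$monitoring_use[0, ]
  v <- course_cost_vector(only_diag, zero$courses$label[1])
  expect_gt(v[["diagnosis"]], 0)
  expect_equal(unname(v[c("treatment", "monitoring", "exacerbations",
                          "end_of_life")]), rep(0, 4))

  expect_error(course_cost_vector(x, "no_such_course"),
               class = "ipf_reference_error")
})

test_that("every component equals the flat-enumeration oracle", {
  for (seed in c(1:8, 42)) {
    x <- random_inputs(seed)
    for (lab in x$courses$label)
      expect_equal(course_cost_vector(x, lab),
                   oracle_course_costs(x, lab),
                   ignore_attr = TRUE, tolerance = 1e-12,
                   label = sprintf("seed %d course %s", seed, lab))
  }
})

test_that("scaling all unit costs scales cost vectors linearly", {
  for (seed in 1:5) {
    x <- random_inputs(seed)
    k <- runif(1, 0.3, 4)
    y <- x
    y$unit_costs$cost_mean <- y$unit_costs$cost_mean * k
    y$unit_costs$cost_min <- y$unit_costs$cost_min * k
    y$unit_costs$cost_max <- y$unit_costs$cost_max * k
    y$drugs$unit_cost <- y$drugs$unit_cost * k
    if (!is.null(y$adverse_events)) {
      y$adverse_events$cost_nonhospitalized <-
        y$adverse_events$cost_nonhospitalized * k
      y$adverse_events$cost_hospitalized <-
        y$adverse_events$cost_hospitalized * k
    }
    y$nonpharma$unit_cost <- y$nonpharma$unit_cost * k
    for (f in names(y$exacerbation))
      y$exacerbation[[f]] <- y$exacerbation[[f]] * k
    for (f in names(y$end_of_life))
      y$end_of_life[[f]] <- y$end_of_life[[f]] * k
    for (lab in x$courses$label)
      expect_equal(course_cost_vector(y, lab),
                   k * course_cost_vector(x, lab),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("diagnosis component is identical across courses", {
  for (seed in 1:5) {
    x <- random_inputs(seed)
    d <- vapply(x$courses$label,
                function(l) course_cost_vector(x, l)[["diagnosis"]],
                numeric(1))
    expect_equal(max(d) - min(d), 0)
  }
})

test_that("calibrated overrides pin components without touching others", {
  x <- random_inputs(7)
  lab <- x$courses$label[2]
  x$overrides <- data.frame(course = lab, component = "monitoring",
                            value = 1234.56)
  v <- course_cost_vector(x, lab)
  o <- oracle_course_costs(x, lab)
  expect_equal(v[["monitoring"]], 1234.56)
  expect_equal(v[c("diagnosis", "treatment", "exacerbations",
                   "end_of_life")],
               o[c("diagnosis", "treatment", "exacerbations",
                   "end_of_life")])
  # other courses unaffected
  other <- setdiff(x$courses$label, lab)[1]
  expect_equal(course_cost_vector(x, other), oracle_course_costs(x, other),
               ignore_attr = TRUE)
})
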