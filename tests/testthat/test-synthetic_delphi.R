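test_that("zero dispersion makes every expert answer the true value", {
  q <- list(delphi_question("q1", "epidemiology.prevalence_per_100k", 12,
                            dispersion = 0))
  panel <- generate_panel(q, n_experts = 7, n_rounds = 3, seed = 99)
  expect_equal(nrow(panel), 21)
  expect_true(all(panel$value == 12))
})

test_that("panels are reproducible by seed and differ across seeds", {
  q <- default_questions(baseline_inputs())
  a <- generate_panel(q, seed = 42)
  b <- generate_panel(q, seed = 42)
  c <- generate_panel(q, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("responses respect question bounds", {
  q <- list(delphi_question("q", "epidemiology.prevalence_per_100k", 12,
                            dispersion = 1.5, lower = 5, upper = 20))
  panel <- generate_panel(q, n_experts = 50, n_rounds = 2, seed = 1)
  expect_true(all(panel$value >= 5 & panel$value <= 20))
})

test_that("later rounds cluster toward the median (dispersion shrinks)", {
  q <- list(delphi_question("q", "exacerbation.treatment_cost", 300,
                            dispersion = 0.4))
  spread_by_round <- vapply(1:3, function(r) {
    s <- 0
    for (seed in 1:30) {
      panel <- generate_panel(q, n_experts = 15, n_rounds = 3, seed = seed)
      v <- panel$value[panel$round == r]
      s <- s + stats::sd(log(v))
    }
    s / 30
  }, numeric(1))
  expect_true(all(diff(spread_by_round) < 0))
})

test_that("consensus_median equals the sort-and-midpoint oracle", {
  expect_equal(unname(consensus_median(data.frame(
    expert_id = 1:3, round = 1, question_id = "q",
    value = c(1, 2, 100)))), 2)
  expect_equal(unname(consensus_median(data.frame(
    expert_id = 1, round = 1, question_id = "q", value = 7.5))), 7.5)

  q <- default_questions(baseline_inputs())
  panel <- generate_panel(q, n_experts = 14, n_rounds = 3, seed = 5)
  med <- consensus_median(panel, round = 3)
  for (id in names(med)) {
    v <- sort(panel$value[panel$round == 3 & panel$question_id == id])
    expect_equal(med[[id]], (v[7] + v[8]) / 2)
  }
  expect_error(consensus_median(panel, round = 9),
               class = "ipf_reference_error")
})

test_that("the median shrugs off a single outlier in panels of >= 3", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:15, 1)
    v <- runif(n, 10, 20)
    panel <- data.frame(expert_id = seq_len(n), round = 1,
                        question_id = "q", value = v)
    spiked <- panel
    spiked$value[sample(n, 1)] <- 1e6
    # an extreme outlier moves the median at most one order statistic and
    # never outside the range of the genuine responses
    v_sorted <- sort(v)
    med <- consensus_median(spiked, 1)[[1]]
    expect_lte(med, v_sorted[min(n, floor(n / 2) + 2)])
    expect_gte(med, v_sorted[1])
  }
})

test_that("agreement_rate counts experts inside the tolerance band", {
  all_same <- data.frame(expert_id = 1:6, round = 1, question_id = "q",
                         value = 4)
  expect_equal(unname(agreement_rate(all_same)), 100)

  # 11 of 14 within 20% of the median
  v <- c(rep(10, 11), 20, 30, 40)
  panel <- data.frame(expert_id = 1:14, round = 1, question_id = "q",
                      value = v)
  expect_equal(unname(agreement_rate(panel, tolerance = 0.2)),
               100 * 11 / 14)

  # zero tolerance, distinct values, even panel: nobody equals the midpoint
  distinct <- data.frame(expert_id = 1:4, round = 1, question_id = "q",
                         value = c(1, 2, 3, 4))
  expect_equal(unname(agreement_rate(distinct, tolerance = 0)), 0)
})

test_that("panel_to_inputs writes consensus values at their target paths", {
  template <- baseline_inputs()
  q <- default_questions(template)
  ids <- vapply(q, function(z) z$question_id, character(1))

  # consensus identical to the template: inputs unchanged
  true_vals <- setNames(vapply(q, function(z) z$true_value, numeric(1)),
                        ids)
  same <- panel_to_inputs(true_vals, q, template)
  expect_equal(same$epidemiology, template$epidemiology)
  expect_equal(same$courses, template$courses)

  shifted <- true_vals
  shifted[["prevalence"]] <- 14
  shifted[["survival_rapid"]] <- 18
  out <- panel_to_inputs(shifted, q, template)
  expect_equal(out$epidemiology$prevalence_per_100k, 14)
  expect_equal(out$courses$median_survival_months[
    out$courses$label == "rapid"], 18)

  bad <- true_vals
  bad[["survival_stable"]] <- 9999  # outside the question bounds
  expect_error(panel_to_inputs(bad, q, template),
               class = "ipf_validation_error")
  expect_error(panel_to_inputs(true_vals[-1], q, template),
               class = "ipf_reference_error")
})

test_that("round-3 medians recover the generating values (15 experts)", {
  q <- default_questions(baseline_inputs(), dispersion = 0.15)
  hits <- 0L
  n_rep <- 200L
  for (seed in seq_len(n_rep)) {
    panel <- generate_panel(q, n_experts = 15, n_rounds = 3, seed = seed)
    med <- consensus_median(panel, round = 3)
    ok <- TRUE
    for (z in q)
      if (abs(med[[z$question_id]] - z$true_value) >
          0.05 * abs(z$true_value)) { ok <- FALSE; break }
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("pipeline recovery error shrinks as panel dispersion shrinks", {
  template <- baseline_inputs()
  # consensus targets the computed route, so drop the calibrated overrides
  template$overrides <- NULL
  base_total <- build_breakdown_table(template)["TOTAL", "weighted"]
  err <- vapply(c(0.3, 0.1, 0.02, 0), function(d) {
    q <- default_questions(template, dispersion = d)
    panel <- generate_panel(q, n_experts = 15, n_rounds = 3, seed = 7)
    out <- panel_to_inputs(consensus_median(panel), q, template)
    abs(build_breakdown_table(out)["TOTAL", "weighted"] - base_total) /
      base_total
  }, numeric(1))
  expect_equal(err[[4]], 0)
  expect_lt(err[[3]], 0.02)
  expect_lt(err[[3]], err[[1]])
})
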