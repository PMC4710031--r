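# Synthetic multi-round Delphi panel: generation, consensus aggregation,
# agreement metrics and write-back of consensus values into a model input
# template. Lets the entire costing pipeline be exercised end-to-end
# without any real expert-elicitation data.

#' Define one panel question
#'
#' @param question_id short identifier.
#' @param target_field dot path into an [ipf_inputs] tree that the
#'   consensus value will be written to, e.g.
#'   `"epidemiology.prevalence_per_100k"`,
#'   `"courses.rapid.median_survival_months"`,
#'   `"exacerbation.treatment_cost"`,
#'   `"unit_costs.hrct.cost_mean"`.
#' @param true_value the generating ("true") value experts estimate.
#' @param dispersion relative spread of round-1 responses (log scale sd);
#'   0 makes every expert answer `true_value` exactly.
#' @param lower,upper admissible bounds; responses are truncated to them.
#' @return a `delphi_question` object.
#' @export
delphi_question <- function(question_id, target_field, true_value,
                            dispersion = 0.15, lower = 0, upper = Inf) {
  if (!is_scalar_num(true_value))
    abort_validation("'true_value' must be a single finite number",
                     question_id)
  if (!is_scalar_num(dispersion) || dispersion < 0)
    abort_validation("'dispersion' must be >= 0", question_id)
  if (true_value < lower || true_value > upper)
    abort_validation("'true_value' must lie within [lower, upper]",
                     question_id)
  structure(list(question_id = question_id, target_field = target_field,
                 true_value = true_value, dispersion = dispersion,
                 lower = lower, upper = upper),
            class = "delphi_question")
}

#' Default question set for a model-input template
#'
#' One question per elicitable scalar of the template: prevalence,
#' incidence, per-course median survivals and exacerbation rates, the
#' three exacerbation cost components and the two end-of-life components.
#' Course proportions are not elicited (they are a constrained composition
#' and would need a dedicated elicitation scheme).
#'
#' @param template an [ipf_inputs] object supplying the true values.
#' @param dispersion relative spread applied to every question.
#' @return list of [delphi_question]s.
#' @export
default_questions <- function(template = baseline_inputs(),
                              dispersion = 0.15) {
  q <- list(
    delphi_question("prevalence", "epidemiology.prevalence_per_100k",
                    template$epidemiology$prevalence_per_100k, dispersion,
                    lower = 0.1, upper = 100),
    delphi_question("incidence", "epidemiology.incidence_per_100k",
                    template$epidemiology$incidence_per_100k, dispersion,
                    lower = 0.01, upper = 100))
  for (i in seq_len(nrow(template$courses))) {
    lab <- template$courses$label[i]
    q <- c(q, list(
      delphi_question(paste0("survival_", lab),
                      paste0("courses.", lab, ".median_survival_months"),
                      template$courses$median_survival_months[i], dispersion,
                      lower = 1, upper = 240),
      delphi_question(paste0("exac_rate_", lab),
                      paste0("courses.", lab, ".exacerbations_per_year"),
                      template$courses$exacerbations_per_year[i], dispersion,
                      lower = 0, upper = 12)))
  }
  q <- c(q, list(
    delphi_question("exac_diagnosis", "exacerbation.diagnosis_cost",
                    template$exacerbation$diagnosis_cost, dispersion),
    delphi_question("exac_treatment", "exacerbation.treatment_cost",
                    template$exacerbation$treatment_cost, dispersion),
    delphi_question("exac_followup", "exacerbation.resource_followup_cost",
                    template$exacerbation$resource_followup_cost, dispersion),
    delphi_question("eol_treatment", "end_of_life.treatment_cost",
                    template$end_of_life$treatment_cost, dispersion),
    delphi_question("eol_visits", "end_of_life.visit_cost",
                    template$end_of_life$visit_cost, dispersion)))
  q
}

#' Generate a synthetic multi-round Delphi panel
#'
#' Responses are log-normal around each question's true value
#' (multiplicative noise: estimates of positive quantities are
#' right-skewed), truncated to the question's bounds. In round r the
#' dispersion shrinks to `dispersion * convergence^(r-1)`: after group
#' feedback, responses cluster ever more tightly around the shared
#' estimand, so the running median converges. (Re-anchoring each round on
#' the previous round's median would instead make the round-1 median's
#' sampling error permanent; see the methods vignette.)
#'
#' @param questions list of [delphi_question]s.
#' @param n_experts panel size (default 15, a realistic national expert
#'   pool for an orphan lung disease).
#' @param n_rounds number of rounds (default 3).
#' @param seed integer seed; identical seeds give identical panels.
#' @param convergence per-round dispersion shrink factor in (0, 1\];
#'   default 0.5.
#' @return data.frame with columns `expert_id`, `round`, `question_id`,
#'   `value`.
#' @export
generate_panel <- function(questions, n_experts = 15, n_rounds = 3,
                           seed = 1, convergence = 0.5) {
  if (!is_count(n_experts) || n_experts < 1)
    abort_validation("'n_experts' must be a positive integer", "n_experts")
  if (!is_count(n_rounds) || n_rounds < 1)
    abort_validation("'n_rounds' must be a positive integer", "n_rounds")
  if (!is_scalar_num(convergence) || convergence <= 0 || convergence > 1)
    abort_validation("'convergence' must lie in (0, 1]", "convergence")
  set.seed(as.integer(seed))
  out <- vector("list", length(questions) * n_rounds)
  k <- 0L
  for (q in questions) {
    for (r in seq_len(n_rounds)) {
      sdlog <- q$dispersion * convergence^(r - 1)
      vals <- if (sdlog == 0 || q$true_value == 0)
        rep(q$true_value, n_experts)
      else q$true_value * exp(stats::rnorm(n_experts, 0, sdlog))
      vals <- pmin(pmax(vals, q$lower), q$upper)
      k <- k + 1L
      out[[k]] <- data.frame(expert_id = seq_len(n_experts), round = r,
                             question_id = q$question_id, value = vals,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-question consensus medians for one round
#'
#' @param responses panel data.frame from [generate_panel()].
#' @param round which round to aggregate (default: the last one present).
#' @return named numeric vector of medians (midpoint of the central pair
#'   for even panel sizes).
#' @export
consensus_median <- function(responses, round = max(responses$round)) {
  r <- responses[responses$round == round, , drop = FALSE]
  if (nrow(r) == 0L)
    abort_reference(sprintf("no responses in round %s", round))
  vapply(split(r$value, r$question_id), stats::median, numeric(1))
}

#' Per-question agreement rate
#'
#' Percent of experts whose response lies within a relative tolerance band
#' around the round median — a stated proxy for the (undefined) consensus
#' degree reported by real panels.
#'
#' @param responses panel data.frame.
#' @param round round to evaluate (default: last).
#' @param tolerance relative half-width of the agreement band (default 0.2,
#'   i.e. within 20% of the median).
#' @return named numeric vector of percents per question.
#' @export
agreement_rate <- function(responses, round = max(responses$round),
                           tolerance = 0.2) {
  check_nonneg(tolerance, "tolerance")
  r <- responses[responses$round == round, , drop = FALSE]
  if (nrow(r) == 0L)
    abort_reference(sprintf("no responses in round %s", round))
  vapply(split(r$value, r$question_id), function(v) {
    med <- stats::median(v)
    100 * mean(abs(v - med) <= tolerance * abs(med))
  }, numeric(1))
}

set_field <- function(inputs, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] %in% c("epidemiology", "exacerbation", "end_of_life",
                      "metadata")) {
    if (length(parts) != 2L || is.null(inputs[[parts[1]]][[parts[2]]]))
      abort_reference(sprintf("cannot resolve target field '%s'", path))
    inputs[[parts[1]]][[parts[2]]] <- value
  } else if (parts[1] == "courses") {
    if (length(parts) != 3L) abort_reference(
      sprintf("cannot resolve target field '%s'", path))
    i <- match(parts[2], inputs$courses$label)
    if (is.na(i) || !parts[3] %in% names(inputs$courses))
      abort_reference(sprintf("cannot resolve target field '%s'", path))
    inputs$courses[i, parts[3]] <- value
  } else if (parts[1] == "unit_costs") {
    if (length(parts) != 3L) abort_reference(
      sprintf("cannot resolve target field '%s'", path))
    i <- match(parts[2], inputs$unit_costs$resource_id)
    if (is.na(i) || !parts[3] %in% names(inputs$unit_costs))
      abort_reference(sprintf("cannot resolve target field '%s'", path))
    inputs$unit_costs[i, parts[3]] <- value
  } else {
    abort_reference(sprintf("cannot resolve target field '%s'", path))
  }
  inputs
}

#' Write consensus values into a model-input template
#'
#' Each question's consensus value is written to its `target_field` in a
#' copy of the template, then the full input validation is re-run (an
#' out-of-bounds consensus therefore fails with a validation error).
#'
#' @param consensus named vector from [consensus_median()].
#' @param questions the [delphi_question] list defining the target paths.
#' @param template [ipf_inputs] object to fill in.
#' @return a validated `ipf_inputs` copy with consensus values applied.
#' @export
panel_to_inputs <- function(consensus, questions, template) {
  x <- template
  for (q in questions) {
    if (!q$question_id %in% names(consensus))
      abort_reference(sprintf("no consensus value for question '%s'",
                              q$question_id))
    v <- unname(consensus[[q$question_id]])
    if (v < q$lower || v > q$upper)
      abort_validation(sprintf(
        "consensus for '%s' (%.6g) outside admissible bounds [%g, %g]",
        q$question_id, v, q$lower, q$upper), q$target_field)
    x <- set_field(x, q$target_field, v)
  }
  suppressWarnings(validate_inputs(x))
  x
}

#' Export a panel to CSV
#'
#' @param responses panel data.frame.
#' @param path output CSV path.
#' @param seed seed to record in a comment-free sidecar metadata JSON
#'   (written next to the CSV as `<path>.meta.json`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(responses, path, seed = NULL) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  if (!is.null(seed))
    jsonlite::write_json(list(seed = seed, n_responses = nrow(responses)),
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
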