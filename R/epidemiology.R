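# Case counting, diagnosis annualization ratio, DEALE mortality.

#' Prevalent cases implied by a prevalence estimate
#'
#' Number of prevalent cases: prevalence per 100,000 times population /
#' 100,000. The exact (unrounded) value is returned; reporting boundaries
#' round half-up via [case_counts()].
#'
#' @param epi epidemiology block of an [ipf_inputs] object.
#' @return unrounded number of prevalent cases.
#' @export
prevalent_cases <- function(epi) {
  epi$prevalence_per_100k * epi$population / 1e5
}

#' Diagnosed cases given a diagnostic rate
#'
#' @param prevalent (unrounded) prevalent case count.
#' @param diagnostic_rate fraction of prevalent cases that are diagnosed.
#' @return unrounded number of diagnosed cases.
#' @export
diagnosed_cases <- function(prevalent, diagnostic_rate) {
  check_fraction(diagnostic_rate, "diagnostic_rate")
  check_nonneg(prevalent, "prevalent")
  prevalent * diagnostic_rate
}

#' Reported case counts
#'
#' Integer case counts for reporting (round half-up); the unrounded values
#' are kept alongside and used by all downstream arithmetic.
#'
#' @param epi epidemiology block of an [ipf_inputs] object.
#' @return list with `prevalent_cases`, `diagnosed_cases` (integers) and
#'   `prevalent_exact`, `diagnosed_exact`.
#' @examples
#' case_counts(list(population = 46039979, prevalence_per_100k = 12,
#'                  incidence_per_100k = 3, diagnostic_rate = 0.85))
#' @export
case_counts <- function(epi) {
  prev <- prevalent_cases(epi)
  diag <- diagnosed_cases(prev, epi$diagnostic_rate)
  list(prevalent_cases = round_half_up(prev),
       diagnosed_cases = round_half_up(diag),
       prevalent_exact = prev,
       diagnosed_exact = diag)
}

#' Incidence-over-prevalence annualization ratio
#'
#' Converts a one-off diagnostic cost into an annual per-prevalent-patient
#' cost: in steady state the fraction of prevalent patients that is newly
#' diagnosed each year equals incidence / prevalence.
#'
#' @param incidence_per_100k new cases per 100,000 person-years.
#' @param prevalence_per_100k cases per 100,000 persons (must be > 0).
#' @return the ratio incidence / prevalence.
#' @export
annualization_ratio <- function(incidence_per_100k, prevalence_per_100k) {
  if (!is_scalar_num(prevalence_per_100k) || prevalence_per_100k <= 0)
    abort_domain("prevalence must be > 0 to form the annualization ratio")
  check_nonneg(incidence_per_100k, "incidence_per_100k")
  incidence_per_100k / prevalence_per_100k
}

#' DEALE annual mortality rate
#'
#' Declining Exponential Approximation to Life Expectancy: the annual
#' mortality rate is approximated by the reciprocal of remaining life
#' expectancy, here 12 / median survival in months, capped at 1. The plain
#' reciprocal (not 1 - exp(-mu)) is used; see the methods vignette.
#'
#' @param median_survival_months median survival after diagnosis, months > 0.
#' @return annual mortality rate as a fraction in (0, 1].
#' @examples
#' deale_annual_mortality(66)  # 0.1818... (18.2%)
#' deale_annual_mortality(15)  # 0.8
#' @export
deale_annual_mortality <- function(median_survival_months) {
  if (any(!is.finite(median_survival_months)) ||
      any(median_survival_months <= 0))
    abort_domain("median survival must be > 0 months")
  pmin(12 / median_survival_months, 1)
}
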