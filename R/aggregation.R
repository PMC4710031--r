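# Course-weighted aggregation: the per-course x per-category breakdown
# table with TOTAL row and weighted column.

#' Total annual cost for one course
#'
#' @param v component vector from [course_cost_vector()].
#' @return EUR per patient-year (sum of the five components).
#' @export
course_total <- function(v) {
  check_nonneg(v, "components")
  sum(v)
}

#' Course-proportion-weighted average
#'
#' @param values named numeric vector, one value per course.
#' @param proportions named numeric vector of population proportions over
#'   the same course set, summing to 1 (within 1e-9).
#' @return the weighted mean.
#' @export
weighted_average <- function(values, proportions) {
  if (!setequal(names(values), names(proportions)) ||
      is.null(names(values)) || is.null(names(proportions)))
    abort_reference("'values' and 'proportions' must be named over the same course set")
  if (abs(sum(proportions) - 1) > 1e-9)
    abort_validation("proportions must sum to 1", "proportions")
  sum(proportions[names(values)] * values)
}

#' Category shares of the weighted cost column
#'
#' Each category's fraction of the weighted total, as unrounded percent.
#' Display rounding to one decimal is the caller's concern; use
#' [format_shares()] for a sum-preserving (largest-remainder) rounding that
#' reproduces printed share tables summing to exactly 100.0.
#'
#' @param weighted_column named numeric vector of weighted per-category
#'   costs (EUR), total > 0.
#' @return named numeric vector of percents (unrounded), summing to 100.
#' @export
category_shares <- function(weighted_column) {
  total <- sum(weighted_column)
  if (!is.finite(total) || total <= 0)
    abort_domain("category shares undefined for a non-positive total")
  100 * weighted_column / total
}

#' Sum-preserving display rounding of percentage shares
#'
#' Largest-remainder rounding to `digits` decimals: shares are floored,
#' then the remaining mass is distributed one unit-in-the-last-place at a
#' time to the largest remainders, so the displayed shares sum to exactly
#' 100 at the displayed precision.
#'
#' @param shares numeric percents (should sum to 100).
#' @param digits decimal places for display (default 1).
#' @return rounded shares summing to 100 at `digits` decimals.
#' @export
format_shares <- function(shares, digits = 1) {
  p <- 10^digits
  fl <- floor(shares * p) / p
  need <- round(sum(shares) * p - sum(fl) * p)
  if (need > 0) {
    rem <- shares - fl
    bump <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[bump] <- fl[bump] + 1 / p
  }
  fl
}

#' Build the full cost breakdown table
#'
#' Computes every course's component vector, appends the TOTAL row (column
#' sums) and the proportion-weighted column. Weighted cells are computed
#' from unrounded component values; rounding is applied only at display /
#' write time.
#'
#' @param inputs an [ipf_inputs] object.
#' @param ae_threshold adverse-event inclusion threshold.
#' @return an `ipf_cost_table`: numeric matrix with rows
#'   `diagnosis, treatment, monitoring, exacerbations, end_of_life, TOTAL`
#'   and one column per course plus `weighted`; course proportions are kept
#'   in the `"proportions"` attribute.
#' @examples
#' tab <- build_breakdown_table(baseline_inputs())
#' round_half_up(tab["TOTAL", "weighted"])  # 26435
#' @export
build_breakdown_table <- function(inputs, ae_threshold = 0.05) {
  validate_inputs(inputs)
  labels <- inputs$courses$label
  prop <- stats::setNames(inputs$courses$proportion, labels)
  cols <- vapply(labels, function(l)
    course_cost_vector(inputs, l, ae_threshold), numeric(5))
  m <- rbind(cols, TOTAL = colSums(cols))
  weighted <- as.vector(m %*% prop[colnames(m)])
  m <- cbind(m, weighted = weighted)
  rownames(m) <- c(COST_CATEGORIES, "TOTAL")
  structure(m, class = "ipf_cost_table", proportions = prop)
}

#' @export
print.ipf_cost_table <- function(x, ...) {
  cat("Annual cost per patient by disease course (EUR)\n")
  m <- round_half_up(unclass(x), 2)
  print(format(m, big.mark = ",", nsmall = 2), quote = FALSE)
  prop <- attr(x, "proportions")
  cat(sprintf("weights: %s\n",
              paste(sprintf("%s=%.0f%%", names(prop), 100 * prop),
                    collapse = ", ")))
  invisible(x)
}
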