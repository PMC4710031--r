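# Shared helpers: classed error conditions and display rounding.

abort_validation <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  stop(errorCondition(msg, field = field,
                      class = c("ipf_validation_error", "ipf_error")))
}

abort_reference <- function(msg) {
  stop(errorCondition(msg, class = c("ipf_reference_error", "ipf_error")))
}

abort_io <- function(msg) {
  stop(errorCondition(msg, class = c("ipf_io_error", "ipf_error")))
}

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("ipf_domain_error", "ipf_error")))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used at every display boundary. Base R's
#' `round()` rounds half to even, which does not reproduce printed currency
#' tables (e.g. 0.125 -> 0.12 instead of 0.13).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, not 2
#' round_half_up(26435.094)  # 26435
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-9

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, field) {
  if (!is_scalar_num(x) || x < 0 || x > 1)
    abort_validation(sprintf("'%s' must be a single number in [0, 1]", field),
                     field)
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!all(is.finite(x)) || any(x < 0))
    abort_validation(sprintf("'%s' must be non-negative and finite", field),
                     field)
  invisible(x)
}

check_cols <- function(df, cols, what) {
  if (!is.data.frame(df))
    abort_validation(sprintf("'%s' must be a data.frame", what), what)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    abort_validation(sprintf("'%s' is missing column(s): %s", what,
                             paste(miss, collapse = ", ")), what)
  invisible(df)
}
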