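## internal validators shared across modules

assert_letters <- function(x, arg = "letters") {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 100)) {
    stop(sprintf("`%s` must be numeric in [0, 100] with no missing values.", arg),
         call. = FALSE)
  }
  invisible(x)
}

assert_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number.", arg), call. = FALSE)
  }
  invisible(x)
}

#' Retention percentage from counts
#'
#' Express a retained/total eye count as a percentage rounded to one decimal,
#' the reporting precision used for eligibility summaries (e.g. 638 of 660
#' eyes with at least 7 first-year assessments is 96.7%).
#'
#' @param kept Number of retained eyes (non-negative).
#' @param total Total number of eyes (positive, `kept <= total`).
#' @return A single number: `100 * kept / total`, rounded to 1 decimal.
#' @examples
#' retention_pct(638, 660)
#' retention_pct(575, 660)
#' @export
retention_pct <- function(kept, total) {
  assert_scalar_number(kept, "kept")
  assert_scalar_number(total, "total")
  if (total <= 0 || kept < 0 || kept > total) {
    stop("`kept` must lie in [0, total] with `total` > 0.", call. = FALSE)
  }
  round(100 * kept / total, 1)
}

## round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
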