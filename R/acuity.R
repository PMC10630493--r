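## ETDRS letter score / logMAR / Snellen conversions.
##
## The working formula throughout is letters = 85 - 50 * logMAR, which
## reproduces the standard chart pairs used in anti-VEGF trial reporting
## (69 letters ~ 20/40, 30 letters ~ 20/252 raw, 100 letters ~ 20/10).

## denominators of the standard 20/x Snellen chart lines
snellen_chart_denominators <- c(
  10, 12.5, 16, 20, 25, 32, 40, 50, 63, 80,
  100, 125, 160, 200, 250, 320, 400, 500, 630, 800
)

#' Convert ETDRS letter scores to logMAR
#'
#' Uses the affine chart relationship letters = 85 - 50 * logMAR, so a
#' perfect 20/20 eye (logMAR 0) reads 85 letters and each chart line
#' (0.1 logMAR) is worth 5 letters.
#'
#' @param letters Numeric vector of ETDRS letter scores in \[0, 100\].
#' @return Numeric vector of logMAR values.
#' @examples
#' letters_to_logmar(c(85, 69, 100))
#' @seealso [logmar_to_letters()], [letters_to_snellen()]
#' @export
letters_to_logmar <- function(letters) {
  assert_letters(letters)
  (85 - letters) / 50
}

#' Convert logMAR to ETDRS letter scores
#'
#' Exact inverse of [letters_to_logmar()]; no rounding or clamping is
#' applied, so values outside the 0--100 letter range are an error.
#'
#' @param logmar Numeric vector of logMAR values in \[-0.3, 1.7\].
#' @return Numeric vector of letter scores.
#' @export
logmar_to_letters <- function(logmar) {
  if (!is.numeric(logmar) || anyNA(logmar)) {
    stop("`logmar` must be numeric with no missing values.", call. = FALSE)
  }
  letters <- 85 - 50 * logmar
  assert_letters(letters, arg = "85 - 50 * logmar")
  letters
}

#' Approximate Snellen equivalent of an ETDRS letter score
#'
#' Maps a letter score to a 20/x Snellen fraction through logMAR:
#' denominator = 20 * 10^logMAR. With `rounding = "raw"` the denominator is
#' rounded to the nearest integer (69 letters gives 20/42, 30 letters gives
#' 20/252); with `rounding = "nearest"` (default) it snaps, on the logMAR
#' scale, to the nearest standard chart line so 69 letters reports as the
#' familiar 20/40 and 24 letters as 20/320. Ties snap to the smaller
#' (better) denominator. The chart list contains one fractional entry
#' (12.5); after snapping, denominators are reported as-is, so 20/12.5 can
#' occur for letter scores around 95.
#'
#' @param letters Numeric vector of ETDRS letter scores in \[0, 100\].
#' @param rounding `"nearest"` (snap to chart lines) or `"raw"`.
#' @return A tibble with columns `letters`, `numerator` (always 20) and
#'   `denominator`.
#' @examples
#' letters_to_snellen(69)                     # 20/40
#' letters_to_snellen(30, rounding = "raw")   # 20/252
#' @export
letters_to_snellen <- function(letters, rounding = c("nearest", "raw")) {
  assert_letters(letters)
  rounding <- match.arg(rounding)
  denom_exact <- 20 * 10^letters_to_logmar(letters)
  denominator <- if (rounding == "raw") {
    as.numeric(round_half_away(denom_exact))
  } else {
    vapply(denom_exact, function(d) {
      dist <- abs(log10(snellen_chart_denominators) - log10(d))
      # which.min takes the first minimum: chart list is ascending, so ties
      # resolve to the smaller denominator
      snellen_chart_denominators[which.min(dist)]
    }, numeric(1))
  }
  tibble::tibble(letters = letters, numerator = 20, denominator = denominator)
}

#' ETDRS letter score from a Snellen fraction
#'
#' Inverse of [letters_to_snellen()] up to rounding:
#' letters = 85 - 50 * log10(denominator / numerator), rounded half away
#' from zero to integer letters and clamped to \[0, 100\].
#'
#' @param denominator Positive numeric vector of Snellen denominators.
#' @param numerator Snellen numerator, fixed at 20 by convention.
#' @return Integer vector of letter scores.
#' @examples
#' snellen_to_letters(40)   # 70 (exact inverse is 69.95)
#' snellen_to_letters(252)  # 30
#' @export
snellen_to_letters <- function(denominator, numerator = 20) {
  if (!is.numeric(denominator) || anyNA(denominator) || any(denominator <= 0)) {
    stop("`denominator` must be a positive number.", call. = FALSE)
  }
  if (!is.numeric(numerator) || anyNA(numerator) || any(numerator <= 0)) {
    stop("`numerator` must be a positive number.", call. = FALSE)
  }
  letters <- round_half_away(85 - 50 * log10(denominator / numerator))
  as.integer(pmin(100, pmax(0, letters)))
}

#' Full letter-score conversion table
#'
#' One row per letter score 0--100 with logMAR and both Snellen renderings;
#' the table the `convert` CLI subcommand prints.
#'
#' @return A tibble with columns `letters`, `logmar`, `snellen_raw`,
#'   `snellen_chart`.
#' @export
acuity_conversion_table <- function() {
  letters <- 0:100
  raw <- letters_to_snellen(letters, rounding = "raw")
  chart <- letters_to_snellen(letters, rounding = "nearest")
  tibble::tibble(
    letters = letters,
    logmar = letters_to_logmar(letters),
    snellen_raw = sprintf("20/%g", raw$denominator),
    snellen_chart = sprintf("20/%g", chart$denominator)
  )
}
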