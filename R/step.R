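## Carry-forward step functions.
##
## The endpoint's interpolation rule: an eye is assumed to hold its last
## measured BCVA value until a newer measurement is taken, giving a
## right-continuous step function over study days.

#' Build a carry-forward step function for one eye
#'
#' Constructs the right-continuous step trajectory implied by the
#' last-observation-carried-forward rule: the value on any day `d` is the
#' letter score of the most recent visit with `day <= d`, and the final
#' segment extends indefinitely (evaluation is always window-clipped).
#'
#' @param days Integer vector of visit days, strictly increasing.
#' @param letters Letter scores observed at those days.
#' @return A `tir_step` object (fields `days`, `letters`).
#' @examples
#' s <- build_step(c(0, 28), c(60, 70))
#' step_value(s, c(0, 27, 28, 100))  # 60 60 70 70
#' @export
build_step <- function(days, letters) {
  if (length(days) == 0) {
    stop("A step trajectory needs at least one visit.", call. = FALSE)
  }
  if (length(days) != length(letters)) {
    stop("`days` and `letters` must have equal length.", call. = FALSE)
  }
  if (anyNA(days) || any(diff(days) <= 0)) {
    stop("`days` must be strictly increasing with no missing values.",
         call. = FALSE)
  }
  assert_letters(letters)
  structure(list(days = as.integer(days), letters = as.numeric(letters)),
            class = "tir_step")
}

#' Evaluate a step trajectory
#'
#' Right-continuous evaluation: `step_value(s, d)` is the letter score of
#' the most recent visit at or before day `d`. Days before the first visit
#' are an error (the function is undefined there).
#'
#' @param step A `tir_step`.
#' @param day Integer vector of days.
#' @return Numeric vector of letter scores.
#' @export
step_value <- function(step, day) {
  stopifnot(inherits(step, "tir_step"))
  if (any(day < step$days[1])) {
    stop("Step trajectory is undefined before its first visit (day ",
         step$days[1], ").", call. = FALSE)
  }
  idx <- findInterval(day, step$days)
  step$letters[idx]
}

#' @export
print.tir_step <- function(x, ...) {
  cat(sprintf("<tir_step> %d segment(s) from day %d; levels %s\n",
              length(x$days), x$days[1],
              paste(head(x$letters, 8), collapse = " ")))
  invisible(x)
}

## segment day-counts of a step clipped to a half-open window:
## returns the number of integer days each segment contributes to
## [window$start, window$end)
segment_days_in_window <- function(step, window) {
  upper <- c(step$days[-1], Inf)
  pmax(0, pmin(window$end, upper) - pmax(window$start, step$days))
}
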