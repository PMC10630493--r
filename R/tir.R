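## Time-in-range computation.
##
## days_in_range counts the integer days d in [start, end) whose
## carry-forward value is at or above the threshold (inclusive, matching
## the ">= 69 letters" convention). Implemented with exact interval
## arithmetic on the step segments; a per-day loop is the test oracle.

#' Time in range for one step trajectory
#'
#' Absolute and relative duration a carry-forward BCVA trajectory spends at
#' or above a letter-score threshold within a half-open analysis window.
#'
#' @param step A `tir_step` from [build_step()]; must be defined at the
#'   window start (guaranteed when the trajectory starts at Day 0).
#' @param threshold Letter-score threshold in \[0, 100\]; comparison is
#'   inclusive (`>=`).
#' @param window Anything [analysis_window()] accepts.
#' @return A one-row tibble: `threshold`, `window`, `days_in_range`,
#'   `weeks_in_range` (= days / 7) and `fraction_in_range` (= days /
#'   window length in days).
#' @examples
#' s <- build_step(c(0, 28, 56), c(60, 70, 65))
#' time_in_range(s, 69, analysis_window(start = 0, end = 84))
#' @export
time_in_range <- function(step, threshold, window) {
  stopifnot(inherits(step, "tir_step"))
  assert_scalar_number(threshold, "threshold")
  assert_letters(threshold, "threshold")
  window <- analysis_window(window)
  if (step$days[1] > window$start) {
    stop("Step trajectory undefined at window start (first visit day ",
         step$days[1], " > ", window$start, ").", call. = FALSE)
  }
  ndays <- segment_days_in_window(step, window)
  days_in_range <- sum(ndays[step$letters >= threshold])
  window_days <- window$end - window$start
  tibble::tibble(
    threshold = threshold,
    window = window$label,
    days_in_range = as.integer(days_in_range),
    weeks_in_range = days_in_range / 7,
    fraction_in_range = days_in_range / window_days
  )
}

#' Convert relative time in range to absolute weeks
#'
#' `fraction * window length in weeks`; e.g. 80% of the 52-week Year-1
#' window is 41.6 weeks.
#'
#' @param fraction Fraction(s) of the window in \[0, 1\].
#' @param window Anything [analysis_window()] accepts.
#' @return Weeks in range (numeric).
#' @examples
#' relative_to_absolute(0.80, "year1")  # 41.6
#' @export
relative_to_absolute <- function(fraction, window) {
  if (!is.numeric(fraction) || anyNA(fraction) ||
      any(fraction < 0 | fraction > 1)) {
    stop("`fraction` must be in [0, 1].", call. = FALSE)
  }
  window <- analysis_window(window)
  fraction * window$length_weeks
}

#' Per-eye time in range across a cohort
#'
#' Builds each eye's carry-forward step function and evaluates
#' [time_in_range()] at one or more thresholds.
#'
#' @param cohort A `tir_cohort` (typically already eligibility-filtered
#'   with [filter_eligible()]).
#' @param threshold Letter-score threshold(s).
#' @param window Anything [analysis_window()] accepts.
#' @return A tibble with one row per eye x threshold: `eye_id`, `arm`,
#'   `baseline_letters`, `threshold`, `window`, `days_in_range`,
#'   `weeks_in_range`, `fraction_in_range`.
#' @export
cohort_tir <- function(cohort, threshold = 69, window = "year1") {
  stopifnot(inherits(cohort, "tir_cohort"))
  window <- analysis_window(window)
  assert_letters(threshold, "threshold")
  visits_by_eye <- split(cohort$visits[c("day", "bcva_letters")],
                         cohort$visits$eye_id)
  per_eye <- lapply(cohort$eyes$eye_id, function(id) {
    v <- visits_by_eye[[id]]
    step <- build_step(v$day, v$bcva_letters)
    out <- lapply(threshold, function(th) time_in_range(step, th, window))
    dplyr::bind_rows(out)
  })
  res <- dplyr::bind_rows(per_eye)
  meta <- cohort$eyes[rep(seq_len(nrow(cohort$eyes)),
                          each = length(threshold)), ]
  dplyr::bind_cols(
    meta[c("eye_id", "arm", "baseline_letters")],
    res
  )
}

#' Threshold sweep of mean time in range
#'
#' For every letter-score threshold on the grid, the unweighted per-arm
#' mean (and SEM) of weeks in range — the data behind the sigmoid
#' threshold-sensitivity curve.
#'
#' @param cohort A `tir_cohort`, already eligibility-filtered.
#' @param window Anything [analysis_window()] accepts.
#' @param thresholds Integer grid, default 0:100 (1-letter increments).
#' @return A tibble ordered by threshold ascending: `arm`, `threshold`,
#'   `mean_weeks`, `sem_weeks`, `n`. Arms with no eyes are omitted with a
#'   warning.
#' @export
threshold_sweep <- function(cohort, window = "year1", thresholds = 0:100) {
  stopifnot(inherits(cohort, "tir_cohort"))
  window <- analysis_window(window)
  if (any(thresholds < 0 | thresholds > 100) ||
      any(thresholds != floor(thresholds))) {
    stop("`thresholds` must be integers in [0, 100].", call. = FALSE)
  }
  thresholds <- as.integer(sort(thresholds))
  visits_by_eye <- split(cohort$visits[c("day", "bcva_letters")],
                         cohort$visits$eye_id)
  # per eye: days-at-or-above for every threshold at once, via level counts
  # (levels are integer letters 0..100) and a reversed cumulative sum
  weeks_mat <- vapply(cohort$eyes$eye_id, function(id) {
    v <- visits_by_eye[[id]]
    step <- build_step(v$day, v$bcva_letters)
    ndays <- segment_days_in_window(step, window)
    counts <- numeric(101)
    lv <- as.integer(round(step$letters)) + 1L
    for (i in seq_along(lv)) counts[lv[i]] <- counts[lv[i]] + ndays[i]
    days_at_least <- rev(cumsum(rev(counts)))  # index t+1 -> days with level >= t
    days_at_least[thresholds + 1L] / 7
  }, numeric(length(thresholds)))
  weeks_mat <- matrix(weeks_mat, nrow = length(thresholds))

  arms <- sort(unique(cohort$eyes$arm))
  out <- lapply(arms, function(a) {
    idx <- which(cohort$eyes$arm == a)
    if (length(idx) == 0) {
      warning("Arm '", a, "' has no eyes; omitted from sweep.", call. = FALSE)
      return(NULL)
    }
    m <- weeks_mat[, idx, drop = FALSE]
    tibble::tibble(
      arm = a,
      threshold = thresholds,
      mean_weeks = rowMeans(m),
      sem_weeks = if (length(idx) > 1) {
        apply(m, 1, sd) / sqrt(length(idx))
      } else {
        0
      },
      n = length(idx)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$threshold, .data$arm)
}

#' Area-under-the-curve change from baseline
#'
#' The AUC-type comparator: the time-averaged letter-score change from
#' baseline over a window. `method = "locf"` averages the carry-forward
#' step function over the integer days of the window (consistent with the
#' time-in-range rule); `method = "trapezoid"` integrates the linear
#' interpolation of the visit values (the convention of earlier AUC
#' analyses), with flat extension beyond the last visit.
#'
#' @param step A `tir_step`.
#' @param baseline Baseline letter score subtracted from the trajectory.
#' @param window Anything [analysis_window()] accepts.
#' @param method `"locf"` (default) or `"trapezoid"`.
#' @return Mean letter-score change from baseline over the window (numeric
#'   scalar).
#' @examples
#' s <- build_step(c(0, 28), c(60, 70))
#' auc_change(s, 60, analysis_window(start = 0, end = 56))  # +5
#' @export
auc_change <- function(step, baseline, window, method = c("locf", "trapezoid")) {
  stopifnot(inherits(step, "tir_step"))
  assert_scalar_number(baseline, "baseline")
  assert_letters(baseline, "baseline")
  method <- match.arg(method)
  window <- analysis_window(window)
  if (step$days[1] > window$start) {
    stop("Step trajectory undefined at window start.", call. = FALSE)
  }
  len <- window$end - window$start
  if (method == "locf") {
    ndays <- segment_days_in_window(step, window)
    sum(ndays * (step$letters - baseline)) / len
  } else {
    knots <- sort(unique(c(
      window$start, window$end,
      step$days[step$days > window$start & step$days < window$end]
    )))
    vals <- approx(step$days, step$letters, xout = knots, rule = 2)$y
    nk <- length(knots)
    integral <- sum(diff(knots) * (vals[-1] + vals[-nk]) / 2)
    integral / len - baseline
  }
}
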