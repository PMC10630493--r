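#' Unadjusted subgroup means of time in range
#'
#' Per arm x baseline-BCVA stratum x threshold mean weeks in range with
#' SEM, unadjusted — the summary behind bar-chart comparisons of time in
#' range by baseline acuity. Strata are defined by letter-score cut points
#' on the baseline value; the default single cut at 69 gives the strata
#' `<69` and `>=69`. SEM uses the sample (n-1) standard deviation; a
#' single-eye stratum reports SEM 0 with `sem_degenerate = TRUE`, and an
#' empty stratum is emitted with `n = 0` and a missing mean.
#'
#' @param tir A tibble from [cohort_tir()] (may contain several
#'   thresholds).
#' @param breaks Increasing letter-score cut points partitioning the
#'   baseline range (default 69).
#' @return A tibble `arm`, `baseline_stratum`, `threshold`, `mean_weeks`,
#'   `sem_weeks`, `n`, `sem_degenerate`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_arm = 30, seed = 3))
#' tir <- cohort_tir(sim$cohort, threshold = c(59, 69, 79))
#' subgroup_means(tir)
#' @export
subgroup_means <- function(tir, breaks = 69) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing.", call. = FALSE)
  }
  edges <- c(-Inf, breaks, Inf)
  labels <- character(length(breaks) + 1)
  labels[1] <- sprintf("<%g", breaks[1])
  if (length(breaks) > 1) {
    for (k in seq_len(length(breaks) - 1)) {
      labels[k + 1] <- sprintf("%g-%g", breaks[k], breaks[k + 1] - 1)
    }
  }
  labels[length(labels)] <- sprintf(">=%g", breaks[length(breaks)])

  dat <- tir
  dat$baseline_stratum <- cut(dat$baseline_letters, breaks = edges,
                              right = FALSE, labels = labels)
  out <- dat |>
    dplyr::group_by(.data$arm, .data$baseline_stratum, .data$threshold) |>
    dplyr::summarise(
      mean_weeks = mean(.data$weeks_in_range),
      sem_weeks = if (dplyr::n() > 1) {
        sd(.data$weeks_in_range) / sqrt(dplyr::n())
      } else {
        0
      },
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      .data$arm,
      baseline_stratum = factor(labels, levels = labels),
      .data$threshold,
      fill = list(n = 0L)
    ) |>
    dplyr::mutate(
      n = as.integer(.data$n),
      sem_degenerate = .data$n == 1L,
      baseline_stratum = as.character(.data$baseline_stratum)
    ) |>
    dplyr::arrange(.data$threshold, .data$arm, .data$baseline_stratum)
  out
}
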