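#' Responder curve over relative time-in-range cut-offs
#'
#' For a fixed BCVA letter-score threshold, the proportion of eyes per arm
#' whose relative time in range meets or exceeds each cut-off from 0% to
#' 100% (1% increments). Both comparisons are inclusive, so the curve
#' starts at 1.0 at the 0% cut-off and is non-increasing. Cut-offs are
#' applied to the exact day-ratio fraction, not to rounded weeks.
#'
#' @param tir A tibble from [cohort_tir()] at a single threshold and
#'   window (`fraction_in_range` in \[0, 1\]).
#' @param cutoffs Integer percent cut-offs, default `0:100`.
#' @return A tibble `arm`, `bcva_threshold`, `cutoff_pct`, `proportion`,
#'   `n`. Arms with no eyes are omitted with a warning.
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_arm = 30, seed = 5))
#' tir <- cohort_tir(sim$cohort, threshold = 69)
#' rc <- responder_curve(tir)
#' rc[rc$cutoff_pct == 80, ]
#' @export
responder_curve <- function(tir, cutoffs = 0:100) {
  if (!all(c("arm", "fraction_in_range") %in% names(tir))) {
    stop("`tir` must contain `arm` and `fraction_in_range`.", call. = FALSE)
  }
  if (length(unique(tir$threshold)) > 1) {
    stop("`tir` mixes BCVA thresholds; compute one curve at a time.",
         call. = FALSE)
  }
  if (any(tir$fraction_in_range < 0 | tir$fraction_in_range > 1)) {
    stop("`fraction_in_range` must lie in [0, 1].", call. = FALSE)
  }
  if (any(cutoffs < 0 | cutoffs > 100)) {
    stop("`cutoffs` must be percentages in [0, 100].", call. = FALSE)
  }
  cutoffs <- sort(unique(as.integer(cutoffs)))
  arms <- sort(unique(tir$arm))
  out <- lapply(arms, function(a) {
    fr <- tir$fraction_in_range[tir$arm == a]
    if (length(fr) == 0) {
      warning("Arm '", a, "' has no eyes; omitted.", call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      arm = a,
      bcva_threshold = tir$threshold[1],
      cutoff_pct = cutoffs,
      proportion = vapply(cutoffs, function(c) mean(fr >= c / 100),
                          numeric(1)),
      n = length(fr)
    )
  })
  dplyr::bind_rows(out)
}
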