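## Cohort container and long-format visit-table I/O.
##
## A cohort is the unit every downstream stage consumes: a validated long
## table of BCVA assessments (one row per eye-day) plus a per-eye summary
## carrying the treatment arm and the Day-0 baseline letter score.

new_tir_cohort <- function(visits, eyes) {
  structure(list(visits = visits, eyes = eyes), class = "tir_cohort")
}

#' Build a cohort from a long visit table
#'
#' Validates and assembles per-eye BCVA trajectories from a long-format
#' table: one row per assessment with the eye identifier, treatment-arm
#' label, study day (Day 0 = randomisation) and ETDRS letter score.
#' Duplicate (eye, day) rows are resolved by keeping the last row in input
#' order, with a warning (database-correction semantics). Eyes without a
#' Day-0 record carry no baseline and are dropped with a warning, since the
#' baseline-adjusted analyses require a Day-0 covariate.
#'
#' @param visits A data frame with columns `eye_id`, `arm`, `day`,
#'   `bcva_letters`.
#' @return A `tir_cohort`: list with `visits` (tibble sorted by eye and day)
#'   and `eyes` (tibble `eye_id`, `arm`, `baseline_letters`, `n_visits`).
#' @examples
#' df <- data.frame(
#'   eye_id = rep(c("a", "b"), each = 2), arm = "AFL",
#'   day = c(0, 28, 0, 35), bcva_letters = c(60, 65, 70, 72)
#' )
#' as_tir_cohort(df)
#' @export
as_tir_cohort <- function(visits) {
  required <- c("eye_id", "arm", "day", "bcva_letters")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols) > 0) {
    stop("Visit table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  visits <- tibble::as_tibble(visits)[required]
  if (!is.numeric(visits$day) || anyNA(visits$day)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(visits$day))))
    stop("Non-numeric or missing `day` at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(visits$day < 0) || any(visits$day != floor(visits$day))) {
    bad <- which(visits$day < 0 | visits$day != floor(visits$day))
    stop("`day` must be a non-negative integer; offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(visits$bcva_letters) || anyNA(visits$bcva_letters) ||
      any(visits$bcva_letters < 0 | visits$bcva_letters > 100)) {
    bad <- which(is.na(visits$bcva_letters) |
                   visits$bcva_letters < 0 | visits$bcva_letters > 100)
    stop("`bcva_letters` must be in [0, 100]; offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  visits$eye_id <- as.character(visits$eye_id)
  visits$arm <- as.character(visits$arm)
  visits$day <- as.integer(visits$day)

  dup <- duplicated(visits[c("eye_id", "day")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate (eye_id, day) row(s) dropped; ",
            "kept the last record in file order.", call. = FALSE)
    visits <- visits[!dup, ]
  }

  arm_per_eye <- tapply(visits$arm, visits$eye_id, function(a) length(unique(a)))
  if (any(arm_per_eye > 1)) {
    stop("Eye(s) assigned to more than one arm: ",
         paste(head(names(arm_per_eye)[arm_per_eye > 1], 5), collapse = ", "),
         call. = FALSE)
  }

  visits <- dplyr::arrange(visits, .data$eye_id, .data$day)
  eyes <- visits |>
    dplyr::group_by(.data$eye_id, .data$arm) |>
    dplyr::summarise(
      baseline_letters = .data$bcva_letters[.data$day == 0][1],
      n_visits = dplyr::n(),
      .groups = "drop"
    )
  no_baseline <- is.na(eyes$baseline_letters)
  if (any(no_baseline)) {
    warning(sum(no_baseline), " eye(s) lacking a Day-0 record excluded: ",
            paste(head(eyes$eye_id[no_baseline], 5), collapse = ", "),
            call. = FALSE)
    keep <- eyes$eye_id[!no_baseline]
    eyes <- eyes[!no_baseline, ]
    visits <- visits[visits$eye_id %in% keep, ]
  }
  if (nrow(eyes) == 0) {
    stop("Cohort is empty after validation.", call. = FALSE)
  }
  new_tir_cohort(visits, eyes)
}

#' Read a visit CSV into a cohort
#'
#' Reads a comma-separated UTF-8 file with header
#' `eye_id,arm,day,bcva_letters` and assembles it with [as_tir_cohort()]
#' (same validation, deduplication and baseline rules).
#'
#' @param path Path to the CSV file.
#' @return A `tir_cohort`.
#' @seealso [write_visits()] for the inverse.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) {
    stop("Visit file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_tir_cohort(df)
}

#' Write a cohort back to the visit CSV format
#'
#' @param cohort A `tir_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(cohort, path) {
  stopifnot(inherits(cohort, "tir_cohort"))
  readr::write_csv(cohort$visits, path, progress = FALSE)
  invisible(path)
}

#' @export
print.tir_cohort <- function(x, ...) {
  cat(sprintf("<tir_cohort> %d eyes, %d visits, arms: %s\n",
              nrow(x$eyes), nrow(x$visits),
              paste(sort(unique(x$eyes$arm)), collapse = ", ")))
  cat(sprintf("  baseline letters: mean %.1f, range %d-%d\n",
              mean(x$eyes$baseline_letters),
              min(x$eyes$baseline_letters), max(x$eyes$baseline_letters)))
  invisible(x)
}

#' Count BCVA assessments inside a window
#'
#' Number of visits per eye with `start <= day < end` (half-open, so a
#' visit on the window's end day is not counted).
#'
#' @param cohort A `tir_cohort`.
#' @param window Anything [analysis_window()] accepts.
#' @return A tibble `eye_id`, `arm`, `n_assessments`.
#' @export
count_assessments <- function(cohort, window) {
  stopifnot(inherits(cohort, "tir_cohort"))
  window <- analysis_window(window)
  inside <- cohort$visits$day >= window$start & cohort$visits$day < window$end
  counts <- table(factor(cohort$visits$eye_id[inside],
                         levels = cohort$eyes$eye_id))
  tibble::tibble(
    eye_id = cohort$eyes$eye_id,
    arm = cohort$eyes$arm,
    n_assessments = as.integer(counts)
  )
}

#' Apply assessment-count eligibility filters
#'
#' Retains eyes with enough BCVA assessments to support a time-in-range
#' calculation: at least `min_year1` (default 7) assessments in Day 0--364
#' for the Year-1 analysis; the Year-2 (Day 365--728) and full-period
#' analyses additionally require at least `min_year2` (default 4)
#' assessments in Day 364--728, i.e. BOTH criteria must hold.
#'
#' @param cohort A `tir_cohort`.
#' @param analysis One of `"year1"`, `"year2"`, `"full"`.
#' @param min_year1,min_year2 Assessment-count thresholds.
#' @return A list of class `tir_eligibility`: `cohort` (the retained
#'   `tir_cohort`), `excluded` (tibble `eye_id,reason,n_year1,n_year2`),
#'   and counts `n_input`, `n_retained`, `pct_retained`.
#' @examples
#' cfg <- sim_config(n_per_arm = 10, seed = 1)
#' sim <- simulate_cohort(cfg)
#' filter_eligible(sim$cohort, "year1")
#' @export
filter_eligible <- function(cohort, analysis = c("year1", "year2", "full"),
                            min_year1 = 7L, min_year2 = 4L) {
  stopifnot(inherits(cohort, "tir_cohort"))
  analysis <- match.arg(analysis)
  n1 <- count_assessments(cohort, "year1")$n_assessments
  n2 <- count_assessments(cohort, "year2")$n_assessments
  ok_y1 <- n1 >= min_year1
  ok <- if (analysis == "year1") ok_y1 else ok_y1 & (n2 >= min_year2)
  reason <- dplyr::case_when(
    ok ~ NA_character_,
    !ok_y1 & analysis != "year1" & n2 < min_year2 ~
      sprintf("<%d year-1 and <%d year-2 assessments", min_year1, min_year2),
    !ok_y1 ~ sprintf("<%d year-1 assessments", min_year1),
    TRUE ~ sprintf("<%d year-2 assessments", min_year2)
  )
  excluded <- tibble::tibble(
    eye_id = cohort$eyes$eye_id[!ok],
    reason = reason[!ok],
    n_year1 = n1[!ok],
    n_year2 = n2[!ok]
  )
  keep_ids <- cohort$eyes$eye_id[ok]
  retained <- new_tir_cohort(
    cohort$visits[cohort$visits$eye_id %in% keep_ids, ],
    cohort$eyes[ok, ]
  )
  structure(
    list(
      cohort = retained,
      excluded = excluded,
      analysis = analysis,
      n_input = nrow(cohort$eyes),
      n_retained = length(keep_ids),
      pct_retained = retention_pct(length(keep_ids), nrow(cohort$eyes))
    ),
    class = "tir_eligibility"
  )
}

#' @export
print.tir_eligibility <- function(x, ...) {
  cat(sprintf("<tir_eligibility '%s'> %d/%d eyes retained (%.1f%%), %d excluded\n",
              x$analysis, x$n_retained, x$n_input, x$pct_retained,
              nrow(x$excluded)))
  invisible(x)
}

#' Write an exclusion report CSV
#'
#' @param eligibility A `tir_eligibility` from [filter_eligible()].
#' @param path Output CSV path (`eye_id,reason,n_year1,n_year2`).
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(eligibility, path) {
  stopifnot(inherits(eligibility, "tir_eligibility"))
  readr::write_csv(eligibility$excluded, path, progress = FALSE)
  invisible(path)
}
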