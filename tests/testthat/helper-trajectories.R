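# Fixture builders shared across tests. All randomness is drawn inside
# withr-free local set.seed() calls in the tests themselves.

# one random carry-forward trajectory starting at day 0
random_step <- function(max_day = 728, max_visits = 20) {
  n <- sample(1:max_visits, 1)
  days <- sort(sample(1:max_day, n - 1))
  days <- c(0L, unique(days))
  letters <- sample(0:100, length(days), replace = TRUE)
  build_step(days, letters)
}

# independent per-day oracle: loop over every integer day in the window
brute_force_tir_days <- function(step, threshold, window) {
  window <- analysis_window(window)
  days <- window$start:(window$end - 1L)
  sum(step_value(step, days) >= threshold)
}

# long visit table for a hand-built cohort
toy_visits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(eye_id = r$eye_id, arm = r$arm, day = r$day,
               bcva_letters = r$letters)
  }))
}

# a regular 4-weekly eye: visits on days 0, 28, ..., 336 (+ optional year 2)
regular_eye <- function(eye_id, arm, letters_y1, year2_days = integer(0),
                        letters_y2 = integer(0)) {
  days <- seq(0L, 336L, by = 28L)
  stopifnot(length(letters_y1) == length(days))
  list(eye_id = eye_id, arm = arm,
       day = c(days, year2_days), letters = c(letters_y1, letters_y2))
}
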