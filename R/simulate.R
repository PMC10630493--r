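## Seeded synthetic-cohort simulator.
##
## Emulates the structure of a three-arm anti-VEGF DMO trial: baselines
## truncated to 24-78 letters, 4-weekly Year-1 visits with +/-1 week
## jitter, 4-16 week Year-2 gaps, occasional missed visits, and a latent
## daily BCVA path (exponential approach to an arm-specific asymptotic
## gain plus AR(1) fluctuation) from which observed letter scores are
## noisy, rounded readings. The latent path is retained as ground truth so
## recovery of arm effects can be tested exactly.

#' Simulator configuration
#'
#' Defaults describe a three-arm anti-VEGF DMO trial cohort: 220 eyes/arm,
#' baseline letter scores with (truncated-distribution) mean 64.8 and
#' spread ~9 letters confined to 24--78, Year-1 visits every 28 days
#' (+/-7-day jitter), Year-2 gaps uniform on 28--112 days, 3% missed
#' visits. Arm gains are calibrated so the true Year-1 mean time in range
#' at threshold 69 is about 41 weeks for `IVT-AFL` versus 37 weeks for
#' `IVT-BEV` (a 4.0-week effect) and 37.7 for `IVT-RAN`.
#'
#' @param arms Named numeric vector: asymptotic letter-score gain per arm.
#' @param n_per_arm Eyes per arm.
#' @param baseline_mean Target mean of the truncated baseline distribution.
#' @param baseline_sd Spread parameter of the (pre-truncation) normal.
#' @param baseline_range Truncation bounds in letters, within \[24, 78\].
#' @param rate_per_week Exponential approach rate of the gain (1/weeks).
#' @param fluct_sd Stationary SD of the AR(1) daily fluctuation (letters).
#' @param ar1_rho Day-to-day AR(1) persistence in \[0, 1).
#' @param noise_sd SD of the per-visit measurement noise (letters).
#' @param year1_interval,year1_jitter Nominal Year-1 visit spacing and
#'   uniform jitter half-width, days.
#' @param year2_gap_range Uniform bounds for Year-2 inter-visit gaps, days.
#' @param miss_prob Probability a scheduled non-baseline visit is missed.
#' @param horizon_day Last simulated study day (default 728, two 364-day
#'   years; use 364 for a Year-1-only cohort).
#' @param seed Integer seed; per-eye substreams are derived from it, so a
#'   cohort is reproducible eye-by-eye.
#' @return A `sim_config` list.
#' @export
sim_config <- function(arms = c("IVT-AFL" = 12.13, "IVT-BEV" = 9.46,
                                "IVT-RAN" = 9.70),
                       n_per_arm = 220L,
                       baseline_mean = 64.8,
                       baseline_sd = 10,
                       baseline_range = c(24, 78),
                       rate_per_week = 0.35,
                       fluct_sd = 3.5,
                       ar1_rho = 0.97,
                       noise_sd = 2.5,
                       year1_interval = 28L,
                       year1_jitter = 7L,
                       year2_gap_range = c(28L, 112L),
                       miss_prob = 0.03,
                       horizon_day = 728L,
                       seed = 1L) {
  if (is.null(names(arms)) || any(names(arms) == "") || anyNA(arms)) {
    stop("`arms` must be a named numeric vector of per-arm gains.",
         call. = FALSE)
  }
  if (n_per_arm < 1) stop("`n_per_arm` must be >= 1.", call. = FALSE)
  if (miss_prob < 0 || miss_prob > 1) {
    stop("`miss_prob` must be in [0, 1].", call. = FALSE)
  }
  if (any(c(baseline_sd, fluct_sd, noise_sd) < 0)) {
    stop("Standard deviations must be >= 0.", call. = FALSE)
  }
  if (ar1_rho < 0 || ar1_rho >= 1) {
    stop("`ar1_rho` must be in [0, 1).", call. = FALSE)
  }
  if (length(baseline_range) != 2 || baseline_range[1] < 24 ||
      baseline_range[2] > 78 || baseline_range[1] >= baseline_range[2]) {
    stop("`baseline_range` must satisfy 24 <= lo < hi <= 78.", call. = FALSE)
  }
  if (year2_gap_range[1] < 1 || year2_gap_range[1] > year2_gap_range[2]) {
    stop("`year2_gap_range` must be increasing and positive.", call. = FALSE)
  }
  if (horizon_day < 364) {
    stop("`horizon_day` must cover at least the Year-1 schedule (364 days).",
         call. = FALSE)
  }
  structure(
    list(
      arms = arms, n_per_arm = as.integer(n_per_arm),
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      baseline_range = baseline_range, rate_per_week = rate_per_week,
      fluct_sd = fluct_sd, ar1_rho = ar1_rho, noise_sd = noise_sd,
      year1_interval = as.integer(year1_interval),
      year1_jitter = as.integer(year1_jitter),
      year2_gap_range = as.integer(year2_gap_range),
      miss_prob = miss_prob, seed = as.integer(seed),
      horizon_day = as.integer(horizon_day)
    ),
    class = "sim_config"
  )
}

## location parameter of a [lo, hi]-truncated normal whose mean equals
## `target`; solved once per simulation
trunc_normal_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  trunc_mean <- function(m) {
    a <- (lo - m) / sd
    b <- (hi - m) / sd
    m + sd * (stats::dnorm(a) - stats::dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  stats::uniroot(function(m) trunc_mean(m) - target,
                 interval = c(lo - 4 * sd, hi + 4 * sd), tol = 1e-8)$root
}

## inverse-CDF draw from the truncated normal (one uniform per eye keeps
## the substream layout fixed)
rtrunc_normal <- function(n, location, sd, lo, hi) {
  if (sd == 0) return(rep(location, n))
  plo <- pnorm(lo, location, sd)
  phi <- pnorm(hi, location, sd)
  qnorm(runif(n, plo, phi), location, sd)
}

per_eye_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 9973 * i) %% (2^31 - 1))
}

## one eye's latent daily path and observed visits; all randomness drawn
## inside the eye's own substream
sim_eye <- function(cfg, eye_seed, gain, baseline_loc) {
  set.seed(eye_seed)
  days <- 0:cfg$horizon_day
  baseline <- round(rtrunc_normal(1, baseline_loc, cfg$baseline_sd,
                                  cfg$baseline_range[1], cfg$baseline_range[2]))
  baseline <- min(cfg$baseline_range[2], max(cfg$baseline_range[1], baseline))

  # fluctuation anchored at 0 on Day 0: the measured baseline IS the
  # enrolment value, so the path starts exactly there and wanders after
  innov_sd <- cfg$fluct_sd * sqrt(1 - cfg$ar1_rho^2)
  innov <- rnorm(length(days) - 1, 0, innov_sd)
  eps <- c(0, stats::filter(innov, cfg$ar1_rho, method = "recursive",
                            init = 0))
  trend <- baseline + gain * (1 - exp(-cfg$rate_per_week * days / 7))
  latent <- pmin(100, pmax(0, trend + eps))

  # Year-1 schedule: every `year1_interval` days through day 364, jittered
  nominal1 <- seq(0L, 364L, by = cfg$year1_interval)
  jitter <- as.integer(round(runif(length(nominal1) - 1,
                                   -cfg$year1_jitter, cfg$year1_jitter)))
  sched1 <- c(0L, pmax(1L, nominal1[-1] + jitter))
  # Year-2 schedule: gaps uniform on year2_gap_range until the horizon
  sched2 <- integer(0)
  t <- max(sched1)
  repeat {
    t <- t + as.integer(round(runif(1, cfg$year2_gap_range[1],
                                    cfg$year2_gap_range[2])))
    if (t > cfg$horizon_day) break
    sched2 <- c(sched2, t)
  }
  sched <- sort(unique(c(sched1, sched2)))
  sched <- sched[sched <= cfg$horizon_day]  # jitter may overshoot the horizon
  missed <- runif(length(sched)) < cfg$miss_prob
  missed[sched == 0L] <- FALSE  # Day 0 always observed
  sched <- sched[!missed]

  noise <- rnorm(length(sched), 0, cfg$noise_sd)
  noise[sched == 0L] <- 0  # Day 0 observation defines the baseline
  observed <- round(latent[sched + 1L] + noise)
  observed <- pmin(100, pmax(0, observed))
  list(baseline = baseline, latent = latent, days = sched,
       letters = observed)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Deterministic given the configuration seed. Each eye's latent BCVA path
#' over days 0--728 is `clamp(baseline + gain * (1 - exp(-rate * d/7)) +
#' AR(1) fluctuation, 0, 100)`; observed visits are the latent value at the
#' (jittered, occasionally missed) visit days plus rounded measurement
#' noise, clamped to \[0, 100\]. Day 0 is always observed.
#'
#' @param config A [sim_config()].
#' @return A list: `cohort` (a `tir_cohort` of the observed visits) and
#'   `truth` (a `tir_ground_truth`: latent daily paths as an eyes x days
#'   matrix, per-eye metadata, and the config).
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_arm = 5, seed = 42))
#' sim$cohort
#' true_tir(sim$truth, threshold = 69, window = "year1")
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  baseline_loc <- trunc_normal_location(
    config$baseline_mean, config$baseline_sd,
    config$baseline_range[1], config$baseline_range[2]
  )
  arm_names <- names(config$arms)
  n_total <- config$n_per_arm * length(arm_names)
  eye_arm <- rep(arm_names, each = config$n_per_arm)
  eye_id <- sprintf("eye-%04d", seq_len(n_total))

  latent <- matrix(NA_real_, nrow = n_total, ncol = config$horizon_day + 1L,
                   dimnames = list(eye_id, NULL))
  rows <- vector("list", n_total)
  baseline <- numeric(n_total)
  for (i in seq_len(n_total)) {
    eye <- sim_eye(config, per_eye_seed(config$seed, i),
                   gain = config$arms[[eye_arm[i]]],
                   baseline_loc = baseline_loc)
    latent[i, ] <- eye$latent
    baseline[i] <- eye$baseline
    rows[[i]] <- tibble::tibble(
      eye_id = eye_id[i], arm = eye_arm[i],
      day = eye$days, bcva_letters = eye$letters
    )
  }
  visits <- dplyr::bind_rows(rows)
  cohort <- as_tir_cohort(visits)
  truth <- structure(
    list(
      latent = latent,
      eyes = tibble::tibble(eye_id = eye_id, arm = eye_arm,
                            baseline_letters = baseline),
      config = config
    ),
    class = "tir_ground_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' True per-arm mean time in range from latent paths
#'
#' The simulator's oracle: time in range computed directly on the latent
#' daily BCVA path (no carry-forward approximation), averaged per arm.
#'
#' @param truth A `tir_ground_truth` from [simulate_cohort()].
#' @param threshold Letter-score threshold (inclusive).
#' @param window Anything [analysis_window()] accepts; must lie within the
#'   simulated horizon.
#' @return A tibble `arm`, `true_mean_weeks`, `n`.
#' @export
true_tir <- function(truth, threshold = 69, window = "year1") {
  stopifnot(inherits(truth, "tir_ground_truth"))
  window <- analysis_window(window)
  if (window$end > ncol(truth$latent)) {
    stop("Window extends beyond the simulated horizon.", call. = FALSE)
  }
  cols <- (window$start:(window$end - 1L)) + 1L
  weeks <- rowSums(truth$latent[, cols, drop = FALSE] >= threshold) / 7
  tibble::tibble(
    arm = sort(unique(truth$eyes$arm)),
    true_mean_weeks = as.numeric(
      tapply(weeks, truth$eyes$arm, mean)[sort(unique(truth$eyes$arm))]
    ),
    n = as.integer(table(truth$eyes$arm)[sort(unique(truth$eyes$arm))])
  )
}

#' Write latent ground-truth paths to CSV
#'
#' Long-format sidecar `eye_id,day,latent_letters`; large (one row per eye
#' per day) and intended for the simulate CLI subcommand.
#'
#' @param truth A `tir_ground_truth`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "tir_ground_truth"))
  n_day <- ncol(truth$latent)
  df <- tibble::tibble(
    eye_id = rep(rownames(truth$latent), each = n_day),
    day = rep(0:(n_day - 1L), times = nrow(truth$latent)),
    latent_letters = as.vector(t(truth$latent))
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
print.tir_ground_truth <- function(x, ...) {
  cat(sprintf("<tir_ground_truth> %d eyes x %d days, arms: %s\n",
              nrow(x$latent), ncol(x$latent),
              paste(names(x$config$arms), collapse = ", ")))
  invisible(x)
}
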