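# helper: minimal tir-shaped tibble
tir_frame <- function(arm, baseline, weeks) {
  tibble::tibble(
    eye_id = sprintf("e%02d", seq_along(arm)),
    arm = arm, baseline_letters = baseline,
    threshold = 69, window = "year1",
    weeks_in_range = weeks,
    fraction_in_range = weeks / 52,
    days_in_range = as.integer(weeks * 7)
  )
}

test_that("constant baseline covariate reduces LS means to raw arm means", {
  dat <- tir_frame(rep(c("A", "B"), each = 4), baseline = rep(65, 8),
                   weeks = c(40, 42, 38, 44, 35, 37, 33, 39))
  expect_warning(fit <- fit_ancova(dat), "constant")
  expect_true(fit$covariate_dropped)
  expect_equal(fit$ls_means$ls_mean, c(41, 36))
  expect_equal(fit$contrasts$diff, 5)
})

test_that("coefficients and LS means match the normal-equations oracle on 6 eyes", {
  dat <- tir_frame(rep(c("A", "B"), each = 3),
                   baseline = c(60, 65, 70, 62, 68, 74),
                   weeks = c(30, 36, 45, 28, 33, 41))
  fit <- fit_ancova(dat)
  # independent oracle: solve X'X b = X'y by hand-built design matrix
  X <- cbind(1, ifelse(dat$arm == "B", 1, 0), dat$baseline_letters)
  y <- dat$weeks_in_range
  beta <- solve(t(X) %*% X, t(X) %*% y)
  mb <- mean(dat$baseline_letters)
  ls_oracle <- c(beta[1] + beta[3] * mb, beta[1] + beta[2] + beta[3] * mb)
  expect_equal(fit$ls_means$ls_mean, ls_oracle, tolerance = 1e-10)
  expect_equal(unname(coef(fit$model)), unname(beta[c(1, 2, 3)]),
               tolerance = 1e-10)
  # CI bounds bracket the estimate; difference identities hold exactly
  expect_true(all(fit$ls_means$ci_lo < fit$ls_means$ls_mean))
  expect_true(all(fit$ls_means$ci_hi > fit$ls_means$ls_mean))
  expect_equal(fit$contrasts$diff,
               fit$ls_means$ls_mean[1] - fit$ls_means$ls_mean[2])
})

test_that("LS means and contrasts agree with emmeans (independent route)", {
  skip_if_not_installed("emmeans")
  sim <- simulate_cohort(sim_config(n_per_arm = 25, seed = 70))
  tir <- cohort_tir(sim$cohort, 69, "year1")
  fit <- fit_ancova(tir)
  em <- emmeans::emmeans(fit$model, "arm")
  em_sum <- as.data.frame(em)
  expect_equal(fit$ls_means$ls_mean, em_sum$emmean, tolerance = 1e-8)
  expect_equal(fit$ls_means$se, em_sum$SE, tolerance = 1e-8)
  expect_equal(fit$ls_means$ci_lo, em_sum$lower.CL, tolerance = 1e-8)
  em_ctr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  expect_equal(fit$contrasts$diff, em_ctr$estimate, tolerance = 1e-8)
  expect_equal(fit$contrasts$p, em_ctr$p.value, tolerance = 1e-8)
})

test_that("LS means are invariant to recentring the baseline covariate", {
  sim <- simulate_cohort(sim_config(n_per_arm = 20, seed = 71))
  tir <- cohort_tir(sim$cohort, 69, "year1")
  fit <- fit_ancova(tir)
  shifted <- tir
  shifted$baseline_letters <- shifted$baseline_letters - 40
  fit2 <- fit_ancova(shifted)
  expect_equal(fit$ls_means$ls_mean, fit2$ls_means$ls_mean, tolerance = 1e-10)
  expect_equal(fit$contrasts$p, fit2$contrasts$p, tolerance = 1e-10)
  # OLS with intercept: grand mean of fitted values equals grand mean outcome
  expect_equal(mean(stats::fitted(fit$model)), mean(tir$weeks_in_range))
})

test_that("degenerate inputs are rejected with clear errors", {
  one_arm <- tir_frame(rep("A", 4), rep(60, 4), c(1, 2, 3, 4))
  expect_error(fit_ancova(one_arm), "at least two treatment arms")
  tiny <- tir_frame(c("A", "A", "B"), c(60, 61, 62), c(1, 2, 3))
  expect_error(fit_ancova(tiny), "at least two eyes")
  mixed <- tir_frame(rep(c("A", "B"), each = 3), 60:65, 1:6)
  mixed$threshold <- c(59, 59, 59, 69, 69, 69)
  expect_error(fit_ancova(mixed), "mixes")
})

test_that("estimate bias shrinks as the cohort grows (parameter recovery)", {
  true_effect <- 4.0
  est_at_n <- function(n, reps, seed0) {
    mean(vapply(seq_len(reps), function(r) {
      cfg <- sim_config(arms = c(A = 12.13, B = 9.46), n_per_arm = n,
                        horizon_day = 364, seed = seed0 + r)
      sim <- simulate_cohort(cfg)
      tir <- cohort_tir(filter_eligible(sim$cohort, "year1")$cohort, 69, "year1")
      fit_ancova(tir)$contrasts$diff[1]
    }, numeric(1)))
  }
  bias_small <- abs(est_at_n(50, 8, 1000) - true_effect)
  bias_large <- abs(est_at_n(200, 8, 2000) - true_effect)
  expect_lt(bias_large, 1.0)
  expect_lt(bias_large, bias_small + 0.5)  # no growth in bias with n
})

test_that("residual diagnostics expose QQ data and a normality screen", {
  sim <- simulate_cohort(sim_config(n_per_arm = 25, seed = 73))
  tir <- cohort_tir(sim$cohort, 69, "year1")
  fit <- fit_ancova(tir)
  d <- residual_diagnostics(fit)
  expect_equal(nrow(d$qq), nrow(tir))
  expect_false(is.unsorted(d$qq$sample))
  expect_equal(sort(d$fitted_resid$residual), d$qq$sample)
  expect_false(d$degenerate)
  expect_true(d$shapiro_w > 0 && d$shapiro_w <= 1)

  # residuals that are exact normal quantiles sit on the identity line
  dat <- tir_frame(rep(c("A", "B"), each = 50), rep(65, 100),
                   weeks = 26 + c(qnorm(ppoints(50)), qnorm(ppoints(50))))
  suppressWarnings(fit_n <- fit_ancova(dat))
  d_n <- residual_diagnostics(fit_n)
  expect_gt(stats::cor(d_n$qq$theoretical, d_n$qq$sample), 0.99)

  # constant residuals flag the degenerate case
  dat_c <- tir_frame(rep(c("A", "B"), each = 3), rep(65, 6),
                     weeks = rep(c(40, 35), each = 3))
  suppressWarnings(fit_c <- fit_ancova(dat_c))
  expect_true(residual_diagnostics(fit_c)$degenerate)
})

test_that("the Shapiro-Wilk screen detects skewed errors in most replicates", {
  set.seed(81)
  hits <- vapply(1:20, function(r) {
    weeks <- pmin(52, stats::rexp(60, rate = 1 / 8))  # strongly skewed
    dat <- tir_frame(rep(c("A", "B"), each = 30),
                     baseline = round(runif(60, 40, 78)), weeks = weeks)
    residual_diagnostics(fit_ancova(dat))$shapiro_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
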