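## Baseline-adjusted ANCOVA with least-squares means.
##
## Outcome (per-eye weeks in range) regressed on treatment arm plus the
## baseline letter score. LS means are model predictions at the pooled mean
## baseline, so the factor coding is immaterial; contrasts use t intervals
## on the OLS residual df, two-sided p, no multiplicity adjustment.

#' Fit a baseline-adjusted ANCOVA on per-eye time in range
#'
#' Ordinary least squares of `weeks_in_range` on treatment arm (unordered
#' factor) plus the baseline BCVA letter score. Least-squares means are the
#' model predictions per arm at the pooled mean baseline; pairwise arm
#' differences carry t-based 95% confidence intervals on the residual
#' degrees of freedom and two-sided unadjusted p-values. If the baseline
#' covariate has zero variance it is dropped with a warning and the fit
#' reduces to a one-way ANOVA, whose LS means are the raw arm means.
#'
#' @param tir A tibble as returned by [cohort_tir()] (columns `eye_id`,
#'   `arm`, `baseline_letters`, `weeks_in_range`; a single threshold and
#'   window).
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return A `tir_ancova`: list with `ls_means` (tibble `arm`, `ls_mean`,
#'   `se`, `ci_lo`, `ci_hi`, `n`), `contrasts` (tibble `arm_a`, `arm_b`,
#'   `diff`, `se`, `ci_lo`, `ci_hi`, `p`), `model` (the `lm` fit),
#'   `baseline_mean`, `covariate_dropped`, `threshold`, `window`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_arm = 40, seed = 7))
#' tir <- cohort_tir(sim$cohort, threshold = 69, window = "year1")
#' fit_ancova(tir)
#' @export
fit_ancova <- function(tir, conf_level = 0.95) {
  required <- c("arm", "baseline_letters", "weeks_in_range")
  if (!all(required %in% names(tir))) {
    stop("`tir` must contain columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(tir$threshold)) > 1 || length(unique(tir$window)) > 1) {
    stop("`tir` mixes thresholds or windows; fit one at a time.",
         call. = FALSE)
  }
  arms <- sort(unique(tir$arm))
  n_arm <- table(factor(tir$arm, levels = arms))
  if (length(arms) < 2) {
    stop("ANCOVA needs at least two treatment arms.", call. = FALSE)
  }
  if (any(n_arm < 2)) {
    stop("Every arm needs at least two eyes; too few in: ",
         paste(names(n_arm)[n_arm < 2], collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(
    weeks = tir$weeks_in_range,
    arm = factor(tir$arm, levels = arms),
    baseline = tir$baseline_letters
  )
  covariate_dropped <- sd(dat$baseline) == 0
  if (covariate_dropped) {
    warning("Baseline covariate is constant; dropped from the model.",
            call. = FALSE)
    model <- lm(weeks ~ arm, data = dat)
  } else {
    model <- lm(weeks ~ arm + baseline, data = dat)
  }
  baseline_mean <- mean(dat$baseline)
  df <- df.residual(model)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  V <- vcov(model)
  beta <- coef(model)

  # prediction rows at the pooled mean baseline, one per arm
  newdata <- data.frame(arm = factor(arms, levels = arms),
                        baseline = baseline_mean)
  X <- model.matrix(delete.response(terms(model)), newdata)
  est <- unname(drop(X %*% beta))
  se <- unname(sqrt(diag(X %*% V %*% t(X))))
  ls_means <- tibble::tibble(
    arm = arms,
    ls_mean = est,
    se = se,
    ci_lo = est - tcrit * se,
    ci_hi = est + tcrit * se,
    n = as.integer(n_arm)
  )

  pairs <- utils::combn(seq_along(arms), 2)
  contrasts <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    L <- X[i, ] - X[j, ]
    d <- unname(drop(L %*% beta))
    sed <- unname(sqrt(drop(t(L) %*% V %*% L)))
    tval <- d / sed
    tibble::tibble(
      arm_a = arms[i], arm_b = arms[j],
      diff = d, se = sed,
      ci_lo = d - tcrit * sed, ci_hi = d + tcrit * sed,
      p = 2 * pt(-abs(tval), df)
    )
  })
  structure(
    list(
      ls_means = ls_means,
      contrasts = dplyr::bind_rows(contrasts),
      model = model,
      baseline_mean = baseline_mean,
      covariate_dropped = covariate_dropped,
      conf_level = conf_level,
      threshold = tir$threshold[1],
      window = tir$window[1]
    ),
    class = "tir_ancova"
  )
}

#' @export
print.tir_ancova <- function(x, digits = 1, ...) {
  cat(sprintf("Baseline-adjusted ANCOVA: weeks in range at threshold >=%s, window %s\n",
              format(x$threshold), x$window))
  if (x$covariate_dropped) cat("  (baseline covariate dropped: zero variance)\n")
  cat("Least-squares means (at pooled mean baseline ",
      sprintf("%.1f letters):\n", x$baseline_mean), sep = "")
  m <- x$ls_means
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-10s %5.*f (%.*f, %.*f)  n = %d\n", m$arm[i],
                digits, m$ls_mean[i], digits, m$ci_lo[i], digits, m$ci_hi[i],
                m$n[i]))
  }
  cat("Pairwise differences:\n")
  d <- x$contrasts
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %s - %s: %+.*f (%.*f, %.*f), p = %.3f\n",
                d$arm_a[i], d$arm_b[i], digits, d$diff[i],
                digits, d$ci_lo[i], digits, d$ci_hi[i], d$p[i]))
  }
  invisible(x)
}

#' Residual diagnostics for an ANCOVA fit
#'
#' The normality screen behind the model's residual assumption: QQ data
#' (theoretical normal vs sample quantiles), residual-versus-fitted pairs,
#' and a Shapiro--Wilk statistic as a numeric complement to the visual
#' check. Constant residuals are a degenerate case and are flagged instead
#' of tested.
#'
#' @param fit A `tir_ancova`.
#' @return A list of class `tir_diagnostics`: `qq` (tibble `theoretical`,
#'   `sample`), `fitted_resid` (tibble `fitted`, `residual`), `shapiro_w`,
#'   `shapiro_p`, `degenerate`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "tir_ancova"))
  r <- unname(stats::residuals(fit$model))
  fitted <- unname(stats::fitted(fit$model))
  degenerate <- sd(r) < 1e-10
  qq <- tibble::tibble(
    theoretical = qnorm(ppoints(length(r))),
    sample = sort(r)
  )
  if (degenerate || length(r) < 3) {
    sw_w <- NA_real_
    sw_p <- NA_real_
  } else {
    sw <- shapiro.test(if (length(r) > 5000) sample(r, 5000) else r)
    sw_w <- unname(sw$statistic)
    sw_p <- sw$p.value
  }
  structure(
    list(
      qq = qq,
      fitted_resid = tibble::tibble(fitted = fitted, residual = r),
      shapiro_w = sw_w,
      shapiro_p = sw_p,
      degenerate = degenerate
    ),
    class = "tir_diagnostics"
  )
}

#' @export
print.tir_diagnostics <- function(x, ...) {
  if (x$degenerate) {
    cat("<tir_diagnostics> degenerate: residuals are constant\n")
  } else {
    cat(sprintf("<tir_diagnostics> n = %d, Shapiro-Wilk W = %.3f (p = %.3g)\n",
                nrow(x$qq), x$shapiro_w, x$shapiro_p))
  }
  invisible(x)
}

#' @importFrom stats terms delete.response
NULL
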