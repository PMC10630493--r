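---
title: "BCVA time in range: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BCVA time in range: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vatir)
```

## The endpoint

Clinical trials in diabetic macular oedema (DMO) usually summarise vision
with the change in best-corrected visual acuity (BCVA) from baseline to a
fixed time point, or with an AUC-type average of that change. Neither says
how *long* an eye kept a functionally meaningful level of vision: two eyes
with identical 12-month change can differ by months in the time they spent
at or above the 69-letter ETDRS score (roughly Snellen 20/40, the driving
requirement in many jurisdictions). *Time in range* (TiR) fills that gap:
for a letter-score threshold $T$ and an analysis window $[a, b)$ of study
days,

$$\mathrm{TiR}(T; a, b) \;=\; \#\{\, d \in [a, b) : V(d) \ge T \,\}
\quad \text{days},$$

where $V(d)$ is the eye's BCVA on day $d$ under the
last-observation-carried-forward (LOCF) convention: an eye is assumed to
hold its most recent measured value until a newer measurement is taken.
`vatir` reports TiR in weeks (`days / 7`) and as a fraction of the window.

Key conventions, each of which a user can override but which together
reproduce the usual trial arithmetic:

* **Windows are half-open in days** with `year1 = [0, 364)`,
  `year2 = [364, 728)`, `full = [0, 728)`. A 364-day year is exactly 52.0
  weeks, which is what makes "80% of Year 1" equal 41.6 weeks; the two
  yearly windows tile the full period, so TiR is additive across them.
* **The threshold comparison is inclusive** (`>= T`), matching the
  "letter score of ≥69" phrasing used in trial reports.
* **Time lives on the integer-day grid.** Days are the native resolution
  of study data; `time_in_range()` uses exact interval arithmetic over the
  step segments, and the test suite proves it identical to a brute-force
  loop over every day of the window.
* **The step function is right-continuous**: on the day of a visit the eye
  already has the new value.

`auc_change()` provides the AUC-of-change comparator. Its default method
(`"locf"`) averages the same step function the TiR uses, so the two
endpoints are internally consistent; `"trapezoid"` reproduces the linear
interpolation convention of earlier AUC analyses. The default is a design
choice, recorded in each fit's output, not a claim that one is right.

## Eligibility

TiR is only as good as the sampling of the trajectory. Following standard
practice for this endpoint, `filter_eligible()` requires at least 7
assessments in Year 1 (roughly one every two months under a 4-weekly
schedule) for the Year-1 analysis, and *both* that criterion and at least 4
assessments in Year 2 for the Year-2 and full-period analyses. Percentages
in eligibility reports are always recomputed from counts
(`retention_pct()`), never transcribed.

Baseline is defined as the Day-0 measurement. Eyes with no Day-0 record
are excluded at ingestion rather than imputed: the baseline-adjusted
analysis needs the covariate, and trial designs guarantee a randomisation
visit. Duplicate (eye, day) rows keep the last record in file order —
database-correction semantics — with a loud warning.

## Cohort statistics

`fit_ancova()` regresses per-eye weeks in range on treatment arm plus
baseline letters by ordinary least squares. Least-squares means are model
predictions at the pooled mean baseline, which makes the factor coding
immaterial (the tests verify invariance to recentring the covariate, and
cross-check every number against **emmeans**). Pairwise contrasts carry
t-based confidence intervals on the residual degrees of freedom and
two-sided p-values with *no* multiplicity adjustment — the endpoint is
descriptive/post-hoc by nature, and the p-values are not meant as
confirmatory tests. A zero-variance baseline drops the covariate with a
warning instead of failing, so the model degrades gracefully to a one-way
ANOVA whose LS means are the raw arm means.

The residual-normality assumption is screened, not assumed:
`residual_diagnostics()` returns QQ and residual-vs-fitted data plus a
Shapiro–Wilk statistic. Constant residuals (possible in tiny balanced toy
data) are flagged as degenerate rather than tested.

`subgroup_means()` gives the unadjusted mean ± SEM view by baseline
stratum. SEM uses the sample (n−1) standard deviation; a single-eye
stratum reports SEM 0 with a degeneracy flag, and empty strata are emitted
with `n = 0` rather than dropped, so tables stay rectangular.

`responder_curve()` computes, for each arm, the proportion of eyes whose
*relative* TiR meets or exceeds each cut-off from 0% to 100% in 1%
increments. Both comparisons are inclusive; cut-offs are applied to the
exact day-ratio fraction rather than to rounded weeks, avoiding double
rounding. The curve therefore starts at exactly 1.0 and is non-increasing.

## Acuity conversions

Letter scores, logMAR and Snellen fractions are linked by
$\text{letters} = 85 - 50\,\log_{10}(\mathrm{MAR})$, the standard ETDRS
chart relationship. `letters_to_snellen()` either reports the raw
denominator $20 \times 10^{\mathrm{logMAR}}$ (69 → 20/42, 30 → 20/252) or
snaps it, on the logMAR scale, to the nearest standard chart line
(69 → 20/40, 59 → 20/63, 79 → 20/25, 24 → 20/320). Snapping distance is
measured in logMAR because chart lines are geometrically spaced; ties go
to the smaller (better) denominator. The chart list includes the
fractional 20/12.5 line, reported as-is.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage can be tested
against a known truth without external data. It emulates the structure of
a three-arm anti-VEGF DMO trial:

* **Baselines**: integer letters from a normal distribution truncated to
  24–78 (the usual enrolment range), with the *truncated* mean set to the
  configured 64.8 letters — the location parameter is solved internally so
  the configured mean is the mean you get.
* **Latent path**: $V(d) = \mathrm{clamp}\{\,b + g\,(1 - e^{-r d / 7}) +
  \varepsilon_d,\; 0, 100\}$ — an exponential approach to an arm-specific
  asymptotic gain $g$ at rate $r = 0.35$/week (most of the gain inside the
  first three months, the qualitative shape of anti-VEGF response), plus a
  daily AR(1) fluctuation $\varepsilon$ with stationary SD 3.5 letters and
  day-to-day persistence 0.97, so fluctuations decorrelate over weeks, the
  time scale of oedema recurrence.
* **Anchoring at Day 0**: the fluctuation starts at 0 and the Day-0
  observation carries no measurement noise, so the measured baseline *is*
  the enrolment value and respects the 24–78 range. Letting noise act on
  Day 0 would produce "enrolled" eyes outside the enrolment criteria.
* **Visits**: Year 1 every 28 days with ±7-day jitter; Year 2 gaps drawn
  uniformly from 28–112 days; each non-baseline visit missed with
  probability 0.03. Day 0 is always observed.
* **Observation model**: latent value plus N(0, 2.5) letters of
  test-retest noise, rounded to integer letters, clamped to 0–100.
* **Reproducibility**: one global seed; each eye draws from its own
  deterministically derived substream, so a cohort is reproducible
  eye-by-eye.

The default arm gains (+12.13, +9.46, +9.70 letters) were fixed once by a
secant search against the generator's own latent-path oracle (`true_tir()`,
20,000 eyes per evaluation) so that the *true* Year-1 mean TiR at
threshold 69 is 41.2, 37.2 and 37.6 weeks — a 4.0-week effect of the first
arm over the second and 3.6 over the third, the magnitude of interest for
this endpoint. Because the truth is defined on the latent daily path, the
carry-forward estimate computed from 4-weekly visits is a slightly
smoothed version of it; the tests verify that this approximation error
shrinks as visits densify.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: the anatomy-driven retreatment rules (the
treatment effect acts directly on BCVA), treatment discontinuation and
dropout, floor effects from progressive disease, within-visit
re-measurement, and any correlation between the two eyes of one patient.
Recovery of a simulated 4.0-week effect shows the *pipeline* is unbiased
and its intervals calibrated under the stated model, not that the model
is the truth of any particular trial.

## Numerical and testing choices

* Problem sizes: the effect-recovery suite uses 200 replicate two-arm
  cohorts of 200 eyes/arm simulated over Year 1 only; the structural
  pipeline checks use one full 660-eye, two-year cohort. These sizes give
  Monte Carlo error well below the 0.5-week recovery tolerance while
  keeping the suite quick to run.
* The per-day brute-force oracle is kept in the test helpers, not the
  package, and the equivalence check is exact (integer days), not a
  tolerance comparison.
* CSV reports round to 1 decimal — the precision at which this endpoint
  is conventionally read — and every report has a `*_full.csv` sidecar at
  full precision so that rounding never limits downstream computation.
* Degenerate inputs fail loudly at validation (letters outside 0–100,
  non-increasing visit days, zero-length windows, arms with one eye)
  rather than propagating.

## Known limitations

LOCF is an assumption, not a measurement: between sparse visits the true
trajectory is unknown, and TiR inherits a discretisation error bounded by
the visit spacing. The Year-2 schedule of the emulated design is variable
(4–16 weeks), so Year-2 TiR is correspondingly coarser — the reason the
eligibility rules exist. The ANCOVA is a single-timepoint-style linear
model on a derived quantity; it does not model within-eye correlation
over thresholds or windows, and nothing here adjusts for multiplicity
across the 101-threshold sweep, which is exploratory by construction.
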