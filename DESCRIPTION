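Package: vatir
Title: Visual Acuity Time in Range for Longitudinal Ophthalmic Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the 'time in range' endpoint for best-corrected visual
    acuity (BCVA) trajectories in ophthalmic trials such as anti-VEGF studies
    in diabetic macular oedema: the absolute (weeks) and relative (percent)
    duration an eye's ETDRS letter score spends at or above a threshold,
    under a last-observation-carried-forward step-function model of
    irregularly sampled visits. Provides cohort ingestion with
    assessment-count eligibility filtering, baseline-adjusted ANCOVA with
    least-squares means and pairwise treatment contrasts, threshold sweeps,
    responder-type cut-off curves, an AUC-of-change comparator, ETDRS
    letter/logMAR/Snellen conversions, a seeded synthetic-cohort simulator
    with known ground truth, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
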