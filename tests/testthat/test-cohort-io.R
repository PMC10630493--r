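test_that("a well-formed visit table ingests to one trajectory per eye", {
  df <- toy_visits(
    list(eye_id = "a", arm = "AFL", day = c(0, 28), letters = c(60, 65)),
    list(eye_id = "b", arm = "BEV", day = c(0, 30), letters = c(70, 72)),
    list(eye_id = "c", arm = "RAN", day = 0, letters = 55)
  )
  cohort <- as_tir_cohort(df)
  expect_s3_class(cohort, "tir_cohort")
  expect_equal(nrow(cohort$eyes), 3)
  expect_equal(sort(cohort$eyes$baseline_letters), c(55, 60, 70))
  expect_equal(cohort$eyes$n_visits[cohort$eyes$eye_id == "a"], 2L)
})

test_that("duplicate (eye, day) rows keep the last record with a warning", {
  df <- data.frame(
    eye_id = "a", arm = "AFL",
    day = c(0, 28, 28), bcva_letters = c(60, 64, 68)
  )
  expect_warning(cohort <- as_tir_cohort(df), "duplicate")
  v <- cohort$visits
  expect_equal(nrow(v), 2)
  expect_equal(v$bcva_letters[v$day == 28], 68)
})

test_that("validation rejects malformed tables and reports the offence", {
  base <- data.frame(eye_id = "a", arm = "AFL", day = 0, bcva_letters = 60)
  expect_error(as_tir_cohort(base[, -4]), "missing column")
  bad_letters <- rbind(base, data.frame(eye_id = "a", arm = "AFL", day = 28,
                                        bcva_letters = 110))
  expect_error(as_tir_cohort(bad_letters), "\\[0, 100\\]")
  bad_day <- rbind(base, data.frame(eye_id = "a", arm = "AFL", day = -3,
                                    bcva_letters = 60))
  expect_error(as_tir_cohort(bad_day), "non-negative")
  two_arms <- rbind(base, data.frame(eye_id = "a", arm = "BEV", day = 28,
                                     bcva_letters = 60))
  expect_error(as_tir_cohort(two_arms), "more than one arm")
})

test_that("eyes without a Day-0 baseline are excluded with a warning", {
  df <- toy_visits(
    list(eye_id = "a", arm = "AFL", day = c(0, 28), letters = c(60, 65)),
    list(eye_id = "b", arm = "AFL", day = c(14, 28), letters = c(70, 72))
  )
  expect_warning(cohort <- as_tir_cohort(df), "Day-0")
  expect_equal(cohort$eyes$eye_id, "a")
})

test_that("write_visits / read_visits round-trips a cohort", {
  sim <- simulate_cohort(sim_config(n_per_arm = 4, seed = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_visits(sim$cohort, path)
  back <- read_visits(path)
  expect_equal(back$visits, sim$cohort$visits)
  expect_equal(back$eyes, sim$cohort$eyes)
})

test_that("assessment counts use the half-open window convention", {
  df <- toy_visits(regular_eye("a", "AFL", rep(60, 13),
                               year2_days = c(364, 420), letters_y2 = c(61, 62)))
  cohort <- as_tir_cohort(df)
  expect_equal(count_assessments(cohort, "year1")$n_assessments, 13L)
  # day 364 falls in year2 (visit exactly on year1's end day is not counted)
  expect_equal(count_assessments(cohort, "year2")$n_assessments, 2L)
  expect_equal(count_assessments(cohort, "full")$n_assessments, 15L)
})

test_that("eligibility applies the 7-in-year-1 and 4-in-year-2 rules", {
  six_y1 <- list(eye_id = "six", arm = "AFL",
                 day = seq(0, 140, by = 28), letters = rep(60, 6))
  full_eye <- regular_eye("ok", "AFL", rep(60, 13),
                          year2_days = seq(364, 700, by = 84),
                          letters_y2 = rep(61, 5))
  y2_short <- regular_eye("y2s", "BEV", rep(60, 13),
                          year2_days = c(400, 500, 600), letters_y2 = rep(61, 3))
  cohort <- as_tir_cohort(toy_visits(six_y1, full_eye, y2_short))

  e1 <- filter_eligible(cohort, "year1")
  expect_setequal(e1$cohort$eyes$eye_id, c("ok", "y2s"))
  expect_equal(e1$excluded$eye_id, "six")
  expect_match(e1$excluded$reason, "<7 year-1")

  ef <- filter_eligible(cohort, "full")
  expect_equal(ef$cohort$eyes$eye_id, "ok")
  expect_setequal(ef$excluded$eye_id, c("six", "y2s"))
  expect_equal(ef$excluded$n_year2[ef$excluded$eye_id == "y2s"], 3L)

  # retained + excluded partition the input, and percentages come from counts
  for (e in list(e1, ef)) {
    expect_equal(nrow(e$cohort$eyes) + nrow(e$excluded), nrow(cohort$eyes))
    expect_equal(e$pct_retained, retention_pct(e$n_retained, e$n_input))
  }
})

test_that("a fully sampled cohort is retained with an empty exclusion report", {
  df <- toy_visits(
    regular_eye("a", "AFL", rep(60, 13), seq(364, 700, 56), rep(60, 7)),
    regular_eye("b", "BEV", rep(65, 13), seq(364, 700, 56), rep(65, 7))
  )
  e <- filter_eligible(as_tir_cohort(df), "full")
  expect_equal(nrow(e$excluded), 0)
  expect_equal(e$pct_retained, 100)
})

test_that("year2/full eligibility is a subset of year1 eligibility", {
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_cohort(sim_config(n_per_arm = 15, miss_prob = 0.25,
                                      seed = 300 + rep))
    ids_y1 <- filter_eligible(sim$cohort, "year1")$cohort$eyes$eye_id
    ids_full <- filter_eligible(sim$cohort, "full")$cohort$eyes$eye_id
    expect_true(all(ids_full %in% ids_y1))
  }
})

test_that("exclusion report writes the documented CSV schema", {
  df <- toy_visits(
    list(eye_id = "six", arm = "AFL", day = seq(0, 140, by = 28),
         letters = rep(60, 6)),
    regular_eye("ok", "AFL", rep(60, 13))
  )
  e <- filter_eligible(as_tir_cohort(df), "year1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_exclusion_report(e, path)
  report <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(report), c("eye_id", "reason", "n_year1", "n_year2"))
  expect_equal(report$eye_id, "six")
})
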