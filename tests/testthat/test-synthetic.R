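test_that("generation is deterministic in the seed", {
  s <- cohort_spec(n_participants = 4, n_weeks = 1, seed = 21)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$minutes, b$minutes)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$truth_participants, b$truth_participants)
  c2 <- generate_cohort(cohort_spec(n_participants = 4, n_weeks = 1, seed = 22))
  expect_false(identical(a$minutes, c2$minutes))
})

test_that("emitted tables are accepted verbatim by the readers", {
  cc <- cached_cohort("tiny", cohort_spec(n_participants = 4, n_weeks = 1,
                                          seed = 21))
  dir <- withr::local_tempdir()
  generate_cohort(cohort_spec(n_participants = 4, n_weeks = 1, seed = 21),
                  out_dir = dir)
  mt <- read_minute_data(file.path(dir, "minutes.csv"))
  expect_identical(attr(mt, "parse_report")$rows_dropped, 0L)
  expect_identical(nrow(mt), nrow(cc$minutes))
  dm <- read_demographics(file.path(dir, "demographics.csv"),
                          file.path(dir, "bmi.csv"))
  expect_identical(nrow(dm$participants), 4L)
})

test_that("noise-free pipeline output reproduces ground truth exactly", {
  cc <- noisefree_cohort()
  res <- process_cohort(minute_table(cc$minutes),
                        demographics_table(cc$demographics, cc$bmi))
  stp <- res$adherence[method == "step"]
  m <- merge(stp, cc$truth_participants, by = "participant_id")
  expect_identical(nrow(m), nrow(stp))
  expect_equal(m$weekly_mvpa_2018, m$true_weekly_mvpa)
  expect_equal(m$weekly_bouted_mvpa_2008, m$true_weekly_bouted)
  expect_identical(m$meets_2018, m$true_meets_2018)
  expect_identical(m$meets_2008, m$true_meets_2008)
})

test_that("archetype construction drives adherence as designed", {
  # pure bout-exerciser cohort: universal step-method adherence
  sp <- cohort_spec(n_participants = 6, n_weeks = 1, seed = 5, noise = FALSE,
                    adherence_model = list(intercept = 20, effects = list()))
  cc <- generate_cohort(sp)
  expect_true(all(cc$truth_participants$archetype == "bout_exerciser"))
  res <- process_cohort(minute_table(cc$minutes),
                        demographics_table(cc$demographics, cc$bmi))
  stp <- res$adherence[method == "step"]
  expect_true(all(stp$meets_2018))
  expect_true(all(stp$meets_2008))

  # pure sporadic-mover cohort: 2018 met, 2008 never (no >=10-minute runs)
  sp2 <- cohort_spec(n_participants = 6, n_weeks = 1, seed = 6, noise = FALSE,
                     adherence_model = list(intercept = -20, effects = list()),
                     archetype_mix = c(sedentary = 0, commuter = 0,
                                       sporadic_mover = 1))
  cc2 <- generate_cohort(sp2)
  res2 <- process_cohort(minute_table(cc2$minutes),
                         demographics_table(cc2$demographics, cc2$bmi))
  stp2 <- res2$adherence[method == "step"]
  expect_true(all(stp2$meets_2018))
  expect_false(any(stp2$meets_2008))
})

test_that("participant-level generator hits its logistic target", {
  eff <- list(sex = c(female = log(0.66)))
  d <- simulate_adherence_cohort(20000, intercept = qlogis(0.25),
                                 effects = eff, seed = 2)
  p_m <- mean(d[sex == "male", meets_2018])
  p_f <- mean(d[sex == "female", meets_2018])
  expect_equal(p_m, 0.25, tolerance = 0.05)
  expect_equal(p_f, plogis(qlogis(0.25) + log(0.66)), tolerance = 0.05)
})

test_that("worked-example fixtures are written and parse", {
  dir <- withr::local_tempdir()
  paths <- generate_worked_examples(dir)
  expect_true(all(file.exists(file.path(dir, c("table_counts.csv",
                                               "bout_patterns.csv",
                                               "boundary_day.csv")))))
  bp <- data.table::fread(file.path(dir, "bout_patterns.csv"))
  for (i in seq_len(nrow(bp))) {
    act <- wearpaga:::parse_bout_pattern(bp$pattern[i])
    expect_identical(nrow(detect_bouts(act)), bp$expected_bouts[i])
  }
  day <- read_minute_data(file.path(dir, "boundary_day.csv"))
  d <- classify_day(exclude_sleep_window(day))
  expect_identical(d$hr_minutes, 599L)
  expect_false(d$is_valid)
})
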