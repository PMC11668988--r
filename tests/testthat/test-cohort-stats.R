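test_that("adult-minute filter keeps only on/after the 18th birthday", {
  bd <- stats::setNames(data.table::as.IDate("2003-06-15"), "P1")
  mt <- data.table::rbindlist(list(
    make_day_minutes("2021-06-14", "P1", 600:609),
    make_day_minutes("2021-06-15", "P1", 600:609),
    make_day_minutes("2021-06-16", "P1", 600:609)))
  out <- filter_adult_minutes(mt, bd)
  expect_identical(sort(unique(format(out$date))),
                   c("2021-06-15", "2021-06-16"))
  expect_identical(nrow(filter_adult_minutes(
    make_day_minutes("2021-06-14", "P1", 600:609), bd)), 0L)
})

test_that("age-group assignment keeps the group with most valid weeks, ties older", {
  cfg <- paga_config(min_hr_minutes_per_day = 2L, min_steps_per_day = 3L,
                     min_valid_days_per_week = 3L)
  # birthday 2021-03-26 (start of week 13): weeks 1-12 at age 29, 13+ at 30
  bd <- stats::setNames(data.table::as.IDate("1991-03-26"), "P1")
  mk_weeks <- function(weeks) {
    days <- as.Date(unlist(lapply(weeks, function(w)
      format(as.Date("2021-01-01") + 7 * (w - 1) + 0:2))))
    data.table::rbindlist(lapply(format(days), function(d)
      minute_table(data.frame(person_id = "P1",
                              datetime = paste(d, c("08:00", "08:01", "08:02")),
                              steps = 1L, heart_rate = 80))))
  }
  # 4 weeks at 29, 8 weeks at 30 -> 30-39, the 4 younger weeks dropped
  cal <- build_wear_calendar(mk_weeks(c(1:4, 13:20)), cfg)
  ag <- assign_age_group(cal, bd)
  expect_identical(as.character(ag$assignments$age_group), "30-39")
  expect_identical(nrow(ag$kept_weeks), 8L)
  expect_true(all(ag$kept_weeks$week >= 13))
  # 4 and 4: tie broken toward the older group
  cal2 <- build_wear_calendar(mk_weeks(c(1:4, 13:16)), cfg)
  ag2 <- assign_age_group(cal2, bd)
  expect_identical(as.character(ag2$assignments$age_group), "30-39")
  # all weeks one group: nothing dropped
  cal3 <- build_wear_calendar(mk_weeks(1:6), cfg)
  ag3 <- assign_age_group(cal3, bd)
  expect_identical(as.character(ag3$assignments$age_group), "18-29")
  expect_identical(nrow(ag3$kept_weeks), 6L)
})

test_that("BMI classification filters outliers and uses [lower, upper) edges", {
  w0 <- data.table::as.IDate("2021-01-01")
  w1 <- data.table::as.IDate("2021-03-01")
  mk <- function(values) data.table::data.table(
    bmi_date = w0 + seq_along(values), bmi_value = values)
  expect_identical(as.character(classify_bmi(mk(c(24, 26)), w0, w1)$bmi_category),
                   "overweight")   # mean 25.0 -> boundary goes up
  r <- classify_bmi(mk(c(200, 24)), w0, w1)
  expect_identical(as.character(r$bmi_category), "normal")
  expect_equal(r$bmi_mean, 24)
  expect_identical(as.character(classify_bmi(mk(17), w0, w1)$bmi_category),
                   "other_or_not_specified")
  expect_identical(as.character(classify_bmi(mk(c(34.9, 35.1)), w0, w1)$bmi_category),
                   "severely_obese")  # mean 35.0
  # out-of-window measurements ignored
  far <- data.table::data.table(bmi_date = w1 + 100, bmi_value = 30)
  expect_identical(as.character(classify_bmi(far, w0, w1)$bmi_category),
                   "other_or_not_specified")
})

test_that("grouped proportions carry Wald intervals and suppression flags", {
  flags <- c(rep(TRUE, 30), rep(FALSE, 30), rep(TRUE, 0), rep(FALSE, 50))
  groups <- factor(c(rep("g1", 60), rep("g2", 50)), levels = c("g1", "g2", "g3"))
  tab <- group_adherence_table(flags, groups)
  g1 <- tab[level == "g1"]
  expect_equal(g1$proportion, 0.5)
  expect_equal(g1$wald_se, sqrt(0.25 / 60))
  expect_equal(g1$ci_low, 0.5 - 1.96 * sqrt(0.25 / 60))
  expect_false(g1$suppressed)
  g2 <- tab[level == "g2"]
  expect_equal(g2$proportion, 0)
  expect_equal(g2$ci_low, 0)          # truncated at zero
  expect_true(g2$suppressed)          # adherent cell below 20
  expect_true(tab[level == "g3", suppressed])
  # totals conserved regardless of suppression
  expect_identical(sum(tab$n), length(flags))
})

test_that("odds ratios follow the cross-product and flag zero cells", {
  r <- odds_ratio_from_counts(1864, 7689, 1069, 2938)
  expect_equal(round(r$or, 2), 0.67)
  expect_equal(r$or, (1864 / 7689) / (1069 / 2938))
  sym <- odds_ratio_from_counts(25, 75, 25, 75)
  expect_equal(sym$or, 1)
  z <- odds_ratio_from_counts(0, 10, 5, 5)
  expect_false(z$defined)
  expect_true(is.na(z$or))
})

test_that("univariate logistic equals the closed-form 2x2 OR", {
  dat <- expand_2x2(40, 60, 25, 75)
  fit <- fit_logistic(dat, "outcome", "exposed", c(exposed = "no"))
  cf <- odds_ratio_from_counts(40, 60, 25, 75)
  expect_equal(fit$terms$odds_ratio, cf$or, tolerance = 1e-6)
  expect_equal(fit$terms$ci_low, cf$ci_low, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("VIF flags collinear designs and passes independent ones", {
  set.seed(5)
  n <- 400
  d <- data.frame(out = runif(n) < 0.4,
                  f1 = factor(sample(c("a", "b"), n, TRUE)),
                  f2 = factor(sample(c("x", "y"), n, TRUE)))
  fit <- fit_logistic(d, "out", c("f1", "f2"))
  expect_true(fit$vif_ok)
  expect_true(all(fit$vif < 1.1))
  d$f3 <- d$f1  # perfectly collinear twin
  fit2 <- suppressWarnings(fit_logistic(d, "out", c("f1", "f3")))
  expect_false(fit2$vif_ok)
})

test_that("pairwise chi-square matches the no-correction Pearson statistic", {
  counts <- data.frame(level = c("male", "female"),
                       n = c(4007L, 9553L), n_adherent = c(1069L, 1864L))
  res <- pairwise_chisq(counts)
  ref <- suppressWarnings(
    chisq.test(matrix(c(1069, 4007 - 1069, 1864, 9553 - 1864), 2,
                      byrow = TRUE), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_lt(res$p, 1e-4)
  expect_true(res$significant)
  # identical proportions: statistic ~ 0, never significant
  same <- data.frame(level = c("a", "b"), n = c(100L, 100L),
                     n_adherent = c(30L, 30L))
  res2 <- pairwise_chisq(same)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  # zero margin is skipped, not fabricated
  zero <- data.frame(level = c("a", "b"), n = c(100L, 50L),
                     n_adherent = c(0L, 0L))
  expect_true(pairwise_chisq(zero)$skipped)
})

test_that("McNemar uses discordant pairs only", {
  # arithmetic oracle: (12 - 8)^2 / 20
  a <- c(rep(TRUE, 12), rep(FALSE, 8), rep(TRUE, 30), rep(FALSE, 30))
  b <- c(rep(FALSE, 12), rep(TRUE, 8), rep(TRUE, 30), rep(FALSE, 30))
  r <- mcnemar_compare_methods(a, b)
  expect_identical(r$b, 12L)
  expect_identical(r$c, 8L)
  expect_equal(r$statistic, 0.8)
  # full agreement
  agree <- mcnemar_compare_methods(a, a)
  expect_equal(agree$statistic, 0)
  expect_equal(agree$p, 1)
  # extreme discordance
  ext <- mcnemar_compare_methods(rep(TRUE, 100), rep(FALSE, 100))
  expect_equal(ext$statistic, 100)
  expect_lt(ext$p, 1e-20)
  expect_true(ext$significant)
})
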