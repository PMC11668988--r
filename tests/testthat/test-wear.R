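test_that("sleep window is half-open [23:00, 05:00)", {
  cfg <- paga_config()
  mt <- make_day_minutes(minute_of_day = c(22 * 60 + 59, 23 * 60, 4 * 60 + 59,
                                           5 * 60))
  kept <- exclude_sleep_window(mt, cfg)
  expect_identical(attr(kept, "removed_minutes"), 2L)
  expect_setequal(kept$minute_of_day, c(22L * 60L + 59L, 5L * 60L))
})

test_that("a complete 1440-minute day keeps exactly 1080 minutes", {
  # derived: 1440 minus the 360 slots of a six-hour window
  expect_identical(sum(!in_sleep_window(0:1439)), 1080L)
  mt <- make_day_minutes(minute_of_day = 0:1439)
  expect_identical(nrow(exclude_sleep_window(mt)), 1080L)
})

test_that("day validity thresholds are inclusive on both criteria", {
  cases <- list(
    list(hr_min = 600L, steps = 100L, valid = TRUE),
    list(hr_min = 599L, steps = 10000L, valid = FALSE),
    list(hr_min = 1080L, steps = 99L, valid = FALSE)
  )
  for (cs in cases) {
    mods <- 300L + seq_len(1080L) - 1L
    hr <- c(rep(80, cs$hr_min), rep(NA_real_, 1080L - cs$hr_min))
    total <- cs$steps
    steps <- c(rep(1L, min(total, 1080L)), rep(0L, 1080L - min(total, 1080L)))
    if (total > 1080L) steps[1L] <- steps[1L] + total - 1080L
    mt <- make_day_minutes(minute_of_day = mods, steps = steps, heart_rate = hr)
    d <- classify_day(mt)
    expect_identical(d$hr_minutes, cs$hr_min)
    expect_identical(d$step_total, as.integer(cs$steps))
    expect_identical(d$is_valid, cs$valid)
  }
})

test_that("missing steps with present heart rate count as HR minutes only", {
  mt <- make_day_minutes(minute_of_day = 300:899,
                         steps = NA_integer_, heart_rate = 80)
  d <- classify_day(mt)
  expect_identical(d$hr_minutes, 600L)
  expect_identical(d$step_total, 0L)
  expect_false(d$is_valid)
})

test_that("weeks anchor on January 1 and the year-end remainder has no week", {
  wk <- assign_week(as.Date(c("2021-01-01", "2021-01-07", "2021-01-08",
                              "2021-12-30", "2021-12-31", "2020-12-31")))
  expect_identical(wk$week, c(1L, 1L, 2L, 52L, NA, NA))  # 2020 is a leap year
  expect_identical(wk$year[6], 2020L)
  # partition: every non-remainder day of a year maps to exactly one
  # 7-day-long week
  days <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = 1)
  w <- assign_week(days)
  expect_identical(sum(is.na(w$week)), 1L)
  expect_true(all(table(w$week[!is.na(w$week)]) == 7L))
})

test_that("wear calendar counts valid weeks and flags inclusion", {
  grid <- 300:1379
  day <- function(id, date) make_day_minutes(date, id, grid,
                                             steps = 1L, heart_rate = 80)
  # 3 valid days in week 1 only -> include
  p1 <- data.table::rbindlist(lapply(c("2021-01-01", "2021-01-03", "2021-01-05"),
                                     function(d) day("P1", d)))
  # 2 valid days per week for 4 weeks -> never a valid week
  p2 <- data.table::rbindlist(lapply(format(as.Date("2021-01-01") +
                                            c(0, 1, 7, 8, 14, 15, 21, 22)),
                                     function(d) day("P2", d)))
  cal <- build_wear_calendar(data.table::rbindlist(list(p1, p2)))
  expect_identical(cal$participants[participant_id == "P1", n_valid_weeks], 1L)
  expect_true(cal$participants[participant_id == "P1", include])
  expect_identical(cal$participants[participant_id == "P2", n_valid_weeks], 0L)
  expect_false(cal$participants[participant_id == "P2", include])
})

test_that("two years of daily valid wear yield 104 valid weeks", {
  # derived by direct count: 52 weeks per year, remainder days excluded;
  # thresholds shrunk so 3 observed minutes make a valid day
  cfg <- paga_config(min_hr_minutes_per_day = 2L, min_steps_per_day = 3L)
  days <- seq(as.Date("2021-01-01"), as.Date("2022-12-31"), by = 1)
  mt <- minute_table(data.frame(
    person_id = "P1",
    datetime = paste(rep(format(days), each = 3),
                     c("08:00", "08:01", "08:02")),
    steps = 1L, heart_rate = 80))
  cal <- build_wear_calendar(mt, cfg)
  expect_identical(cal$participants$n_valid_weeks, 104L)
  expect_identical(nrow(cal$weeks[is_valid == TRUE]), 104L)
})

test_that("day validity is monotone in added signal", {
  base_mods <- 300L + seq_len(700L) - 1L
  mt <- make_day_minutes(minute_of_day = base_mods, steps = 1L, heart_rate = 80)
  before <- classify_day(mt)
  extra <- make_day_minutes(minute_of_day = 1001:1010, steps = 5L,
                            heart_rate = 90)
  after <- classify_day(data.table::rbindlist(list(mt, extra)))
  expect_true(after$hr_minutes >= before$hr_minutes)
  expect_true(after$step_total >= before$step_total)
  expect_true(!before$is_valid || after$is_valid)
})
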