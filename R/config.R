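#' Pipeline configuration
#'
#' Builds the configuration object holding every numeric constant used by the
#' pipeline: the overnight sleep window, wear-validity thresholds, cadence and
#' percent-of-maximum-heart-rate intensity cutpoints, guideline targets, bout
#' rules, BMI handling, small-cell suppression, and test alpha levels. The
#' defaults reproduce the published analysis parameters exactly; override any
#' of them by name.
#'
#' @param sleep_window_start,sleep_window_end Clock times ("HH:MM") bounding
#'   the presumed sleep/nonwear window, interpreted as the half-open overnight
#'   interval `[start, end)`. Defaults 23:00 and 05:00.
#' @param min_hr_minutes_per_day Minimum minutes bearing a heart-rate value
#'   (after sleep exclusion) for a valid wear day. Default 600 (10 h).
#' @param min_steps_per_day Minimum daily step total for a valid wear day.
#'   Default 100.
#' @param min_valid_days_per_week Valid days required for a valid week.
#'   Default 3.
#' @param step_thresholds Named numeric vector, steps/min lower bounds for
#'   light, moderate and vigorous cadence intensity. Defaults 60/100/130.
#' @param hr_fractions Named numeric vector, fractions of maximum heart rate
#'   bounding light, moderate and vigorous intensity. Defaults 0.57/0.64/0.77.
#' @param max_hr_intercept,max_hr_slope Maximum-heart-rate prediction
#'   `intercept - slope * age` in bpm (ACSM formula 208 - 0.7 x age).
#' @param mvpa_target Weekly moderate-to-vigorous activity target in
#'   weighted minutes (moderate + `vpa_weight` x vigorous). Default 150.
#' @param vpa_weight Weight of a vigorous minute in MVPA. Default 2.
#' @param bout_min_duration Minimum bout span in minutes. Default 10.
#' @param bout_max_interruption Cumulative below-threshold minutes tolerated
#'   inside one bout. Default 2.
#' @param weekly_scaling `"extrapolate"` (scale valid-day MVPA to a 7-day
#'   equivalent, the default) or `"raw_sum"` (sum over valid days only).
#' @param bmi_lower_outlier,bmi_upper_outlier BMI measurements outside
#'   `[12, 150]` kg/m^2 are discarded as implausible.
#' @param bmi_underweight_cutoff BMI below 18.5 kg/m^2 is pooled with the
#'   "other or not specified" category.
#' @param suppression_threshold Any displayed cell with fewer participants
#'   than this is suppressed. Default 20.
#' @param alpha_primary,alpha_chisq,alpha_mcnemar Significance levels: 0.05
#'   for regression Wald tests, 0.0012 for Bonferroni-adjusted pairwise
#'   chi-square, 0.0008 for Bonferroni-adjusted McNemar comparisons.
#' @param continuity_correction Logical; apply the continuity correction in
#'   chi-square/McNemar statistics. Default `FALSE`.
#' @param random_seed Integer seed recorded in run manifests.
#'
#' @return An object of class `paga_config` (a named list).
#' @examples
#' cfg <- paga_config()
#' cfg$step_thresholds
#' paga_config(mvpa_target = 75)$mvpa_target
#' @export
paga_config <- function(sleep_window_start = "23:00",
                        sleep_window_end = "05:00",
                        min_hr_minutes_per_day = 600L,
                        min_steps_per_day = 100L,
                        min_valid_days_per_week = 3L,
                        step_thresholds = c(light = 60, moderate = 100, vigorous = 130),
                        hr_fractions = c(light = 0.57, moderate = 0.64, vigorous = 0.77),
                        max_hr_intercept = 208,
                        max_hr_slope = 0.7,
                        mvpa_target = 150,
                        vpa_weight = 2,
                        bout_min_duration = 10L,
                        bout_max_interruption = 2L,
                        weekly_scaling = c("extrapolate", "raw_sum"),
                        bmi_lower_outlier = 12,
                        bmi_upper_outlier = 150,
                        bmi_underweight_cutoff = 18.5,
                        suppression_threshold = 20L,
                        alpha_primary = 0.05,
                        alpha_chisq = 0.0012,
                        alpha_mcnemar = 0.0008,
                        continuity_correction = FALSE,
                        random_seed = 1L) {
  weekly_scaling <- match.arg(weekly_scaling)

  cfg <- list(
    sleep_window_start = .parse_clock(sleep_window_start),
    sleep_window_end = .parse_clock(sleep_window_end),
    min_hr_minutes_per_day = as.integer(min_hr_minutes_per_day),
    min_steps_per_day = as.integer(min_steps_per_day),
    min_valid_days_per_week = as.integer(min_valid_days_per_week),
    step_thresholds = .named3(step_thresholds, "step_thresholds"),
    hr_fractions = .named3(hr_fractions, "hr_fractions"),
    max_hr_intercept = as.numeric(max_hr_intercept),
    max_hr_slope = as.numeric(max_hr_slope),
    mvpa_target = as.numeric(mvpa_target),
    vpa_weight = as.numeric(vpa_weight),
    bout_min_duration = as.integer(bout_min_duration),
    bout_max_interruption = as.integer(bout_max_interruption),
    weekly_scaling = weekly_scaling,
    bmi_lower_outlier = as.numeric(bmi_lower_outlier),
    bmi_upper_outlier = as.numeric(bmi_upper_outlier),
    bmi_underweight_cutoff = as.numeric(bmi_underweight_cutoff),
    suppression_threshold = as.integer(suppression_threshold),
    alpha_primary = as.numeric(alpha_primary),
    alpha_chisq = as.numeric(alpha_chisq),
    alpha_mcnemar = as.numeric(alpha_mcnemar),
    continuity_correction = isTRUE(continuity_correction),
    random_seed = as.integer(random_seed)
  )

  # every threshold strictly positive, ordered light < moderate < vigorous
  stopifnot(
    all(cfg$step_thresholds > 0), !is.unsorted(cfg$step_thresholds, strictly = TRUE),
    all(cfg$hr_fractions > 0), !is.unsorted(cfg$hr_fractions, strictly = TRUE),
    cfg$min_hr_minutes_per_day > 0, cfg$min_steps_per_day > 0,
    cfg$min_valid_days_per_week > 0, cfg$mvpa_target > 0, cfg$vpa_weight > 0,
    cfg$bout_min_duration > 0, cfg$bout_max_interruption >= 0,
    cfg$bmi_lower_outlier > 0, cfg$bmi_upper_outlier > cfg$bmi_lower_outlier,
    cfg$suppression_threshold > 0
  )
  structure(cfg, class = "paga_config")
}

# "HH:MM" -> minute of day [0, 1439]
.parse_clock <- function(x) {
  if (is.numeric(x)) {
    m <- as.integer(x)
  } else {
    parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
      stop("clock time must be 'HH:MM', got '", x, "'", call. = FALSE)
    m <- as.integer(parts[1L]) * 60L + as.integer(parts[2L])
  }
  if (m < 0L || m > 1439L) stop("clock time out of range: ", x, call. = FALSE)
  m
}

.named3 <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) != 3L) stop(what, " must have 3 values (light, moderate, vigorous)")
  names(x) <- c("light", "moderate", "vigorous")
  x
}

#' @export
print.paga_config <- function(x, ...) {
  cat("<paga_config>\n")
  cat(sprintf("  sleep window: [%02d:%02d, %02d:%02d) (clock time)\n",
              x$sleep_window_start %/% 60, x$sleep_window_start %% 60,
              x$sleep_window_end %/% 60, x$sleep_window_end %% 60))
  cat(sprintf("  valid day: >=%d HR minutes and >=%d steps; valid week: >=%d valid days\n",
              x$min_hr_minutes_per_day, x$min_steps_per_day, x$min_valid_days_per_week))
  cat(sprintf("  cadence cutpoints (steps/min): %s\n",
              paste(names(x$step_thresholds), x$step_thresholds, sep = "=", collapse = ", ")))
  cat(sprintf("  %%HRmax cutpoints: %s (HRmax = %g - %g x age)\n",
              paste(names(x$hr_fractions), x$hr_fractions, sep = "=", collapse = ", "),
              x$max_hr_intercept, x$max_hr_slope))
  cat(sprintf("  MVPA target: %g min/week (vigorous x%g); bouts: >=%d min, <=%d min interruption\n",
              x$mvpa_target, x$vpa_weight, x$bout_min_duration, x$bout_max_interruption))
  invisible(x)
}

DEVICE_LEVELS <- c("sedentary", "lightly_active", "fairly_active", "very_active")
SEX_LEVELS <- c("male", "female", "other_or_not_specified")
RACE_LEVELS <- c("hispanic", "nh_asian_pi", "nh_black", "nh_white",
                 "two_or_more", "other_or_not_specified")
AGE_GROUP_LEVELS <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70+")
BMI_LEVELS <- c("normal", "overweight", "obese", "severely_obese",
                "other_or_not_specified")
METHOD_LEVELS <- c("step", "hr", "device")
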