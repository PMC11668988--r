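#' Cadence-based intensity classification
#'
#' Classifies minutes by steps/min against the configured cutpoints
#' (defaults: light 60, moderate 100, vigorous 130). Thresholds are
#' inclusive at the lower edge of the higher category, so 100 steps/min is
#' moderate and 130 is vigorous; missing steps are `unclassifiable`.
#'
#' @param steps Numeric vector of steps/min (NA allowed).
#' @param config A [paga_config()].
#' @return Factor with levels sedentary/light/moderate/vigorous/unclassifiable.
#' @export
step_intensity <- function(steps, config = paga_config()) {
  if (any(steps < 0, na.rm = TRUE))
    stop("negative steps reached step_intensity; drop them at ingest")
  th <- config$step_thresholds
  .threshold_label(steps, th)
}

#' Predicted maximum heart rate
#'
#' ACSM age-predicted maximum heart rate: `208 - 0.7 x age` bpm, unrounded.
#' Only adult ages are accepted (minute data before the 18th birthday is
#' excluded upstream).
#'
#' @param age Age in years (>= 18); completed years are used throughout the
#'   pipeline.
#' @param config A [paga_config()].
#' @return Numeric bpm.
#' @examples
#' max_heart_rate(40) # 180
#' @export
max_heart_rate <- function(age, config = paga_config()) {
  if (any(age < 18, na.rm = TRUE)) stop("max_heart_rate requires age >= 18")
  config$max_hr_intercept - config$max_hr_slope * age
}

#' Percent-of-maximum-heart-rate intensity classification
#'
#' Classifies minutes by the fraction `heart_rate / max_hr` against the
#' configured cutpoints (defaults: light 0.57, moderate 0.64, vigorous 0.77),
#' inclusive at the lower edge of the higher category. Missing heart rate is
#' `unclassifiable`.
#'
#' @param heart_rate Numeric bpm (NA allowed).
#' @param max_hr Predicted maximum heart rate (bpm), scalar or vector.
#' @param config A [paga_config()].
#' @return Factor as in [step_intensity()].
#' @export
hr_intensity <- function(heart_rate, max_hr, config = paga_config()) {
  if (any(max_hr <= 0)) stop("max_hr must be positive")
  if (any(heart_rate <= 0, na.rm = TRUE))
    stop("nonpositive heart rate reached hr_intensity; drop at ingest")
  .threshold_label(heart_rate / max_hr, config$hr_fractions)
}

#' Device-label intensity classification
#'
#' Maps the device's own categorical output onto the four intensity classes:
#' sedentary, lightly_active -> light, fairly_active -> moderate,
#' very_active -> vigorous; missing labels are `unclassifiable`.
#'
#' @param device_label Character vector of device labels (NA allowed).
#' @param config A [paga_config()] (unused, kept for interface symmetry).
#' @return Factor as in [step_intensity()].
#' @export
device_intensity <- function(device_label, config = paga_config()) {
  lab <- as.character(device_label)
  unknown <- !is.na(lab) & !(lab %in% DEVICE_LEVELS)
  if (any(unknown))
    stop("unknown device label(s): ", paste(unique(lab[unknown]), collapse = ", "))
  out <- rep("unclassifiable", length(lab))
  out[!is.na(lab)] <- c(sedentary = "sedentary", lightly_active = "light",
                        fairly_active = "moderate", very_active = "vigorous"
  )[lab[!is.na(lab)]]
  factor(out, levels = INTENSITY_LEVELS)
}

# shared thresholding: x < light -> sedentary, [light, moderate) -> light,
# [moderate, vigorous) -> moderate, >= vigorous -> vigorous, NA -> unclassifiable
.threshold_label <- function(x, cuts) {
  out <- rep("unclassifiable", length(x))
  ok <- !is.na(x)
  out[ok & x < cuts[["light"]]] <- "sedentary"
  out[ok & x >= cuts[["light"]] & x < cuts[["moderate"]]] <- "light"
  out[ok & x >= cuts[["moderate"]] & x < cuts[["vigorous"]]] <- "moderate"
  out[ok & x >= cuts[["vigorous"]]] <- "vigorous"
  factor(out, levels = INTENSITY_LEVELS)
}

#' Age in completed years at a date
#'
#' @param birth_date,at_date Date vectors (recycled).
#' @return Integer completed years.
#' @export
age_at <- function(birth_date, at_date) {
  birth_date <- as.POSIXlt(data.table::as.IDate(birth_date))
  at_date <- as.POSIXlt(data.table::as.IDate(at_date))
  age <- at_date$year - birth_date$year
  before_birthday <- (at_date$mon < birth_date$mon) |
    (at_date$mon == birth_date$mon & at_date$mday < birth_date$mday)
  as.integer(age - before_birthday)
}

#' Label every minute under one intensity algorithm
#'
#' Vectorised labelling of a minute table. For the HR method each minute's
#' threshold uses the participant's age in completed years on that date
#' (thresholds shift on birthdays), which requires `birth_dates`.
#'
#' @param minutes Minute table.
#' @param method One of `"step"`, `"hr"`, `"device"`.
#' @param config A [paga_config()].
#' @param birth_dates Named `IDate` vector (names = participant ids);
#'   required for `method = "hr"`.
#' @return Factor of per-minute labels aligned with `minutes` rows.
#' @export
label_minutes <- function(minutes, method = c("step", "hr", "device"),
                          config = paga_config(), birth_dates = NULL) {
  method <- match.arg(method)
  switch(method,
    step = step_intensity(minutes$steps, config),
    device = device_intensity(minutes$device_label, config),
    hr = {
      if (is.null(birth_dates)) stop("HR method needs birth_dates")
      bd <- birth_dates[minutes$participant_id]
      if (anyNA(bd)) stop("birth date missing for some participants")
      age <- age_at(bd, minutes$date)
      hr_intensity(minutes$heart_rate, max_heart_rate(age, config), config)
    })
}

#' Daily intensity profile under one algorithm
#'
#' Tallies one valid day's minutes into the five labels for the chosen
#' method. Minutes lacking the method's signal are `unclassifiable`; the
#' counts always sum to the day's wear-minute count.
#'
#' @param day_minutes Minute table rows for one participant-date.
#' @param method One of `"step"`, `"hr"`, `"device"`.
#' @param participant_age_at_day Completed years on that date (HR method).
#' @param config A [paga_config()].
#' @return Named integer vector over [INTENSITY_LEVELS].
#' @export
daily_profile <- function(day_minutes, method = c("step", "hr", "device"),
                          participant_age_at_day = NULL,
                          config = paga_config()) {
  method <- match.arg(method)
  labels <- switch(method,
    step = step_intensity(day_minutes$steps, config),
    device = device_intensity(day_minutes$device_label, config),
    hr = {
      if (is.null(participant_age_at_day))
        stop("HR method needs participant_age_at_day")
      hr_intensity(day_minutes$heart_rate,
                   max_heart_rate(participant_age_at_day, config), config)
    })
  tab <- table(labels)
  out <- stats::setNames(as.integer(tab[INTENSITY_LEVELS]), INTENSITY_LEVELS)
  out[is.na(out)] <- 0L
  out
}

#' Intensity minute labels used by the package
#' @format Character vector of the five per-minute intensity labels.
#' @export
INTENSITY_LEVELS <- c("sedentary", "light", "moderate", "vigorous", "unclassifiable")
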