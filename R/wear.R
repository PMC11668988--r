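#' Remove the presumed sleep window
#'
#' Drops every record whose clock time falls inside the half-open overnight
#' window `[sleep_window_start, sleep_window_end)` (default `[23:00, 05:00)`).
#' With the defaults this removes exactly 360 of the 1440 possible minute
#' slots per calendar day, so a fully observed day retains 1080 minutes.
#' The number of removed records is attached as attribute `removed_minutes`.
#'
#' @param minutes A minute table from [read_minute_data()] / [minute_table()].
#' @param config A [paga_config()].
#' @return The filtered minute table.
#' @export
exclude_sleep_window <- function(minutes, config = paga_config()) {
  keep <- !in_sleep_window(minutes$minute_of_day, config)
  out <- minutes[keep]
  data.table::setattr(out, "removed_minutes", sum(!keep))
  out[]
}

#' Is a clock minute inside the sleep window?
#'
#' @param minute_of_day Integer vector, minutes after midnight (0-1439).
#' @param config A [paga_config()].
#' @return Logical vector.
#' @export
in_sleep_window <- function(minute_of_day, config = paga_config()) {
  s <- config$sleep_window_start
  e <- config$sleep_window_end
  if (s == e) return(rep(FALSE, length(minute_of_day)))
  if (s < e) minute_of_day >= s & minute_of_day < e   # same-day window
  else minute_of_day >= s | minute_of_day < e         # overnight window
}

#' Classify one midnight-anchored day of records
#'
#' A valid wear day needs at least `min_hr_minutes_per_day` minutes bearing a
#' heart-rate value and a step total of at least `min_steps_per_day`, both
#' inclusive, counted after sleep-window exclusion. Missing steps on a minute
#' with heart rate present contribute 0 steps but still count as an HR
#' minute: the two criteria are independent.
#'
#' @param day_minutes Minute table rows for a single calendar date.
#' @param config A [paga_config()].
#' @return List with `hr_minutes`, `step_total`, `is_valid`.
#' @export
classify_day <- function(day_minutes, config = paga_config()) {
  if (nrow(day_minutes) && length(unique(day_minutes$date)) != 1L)
    stop("classify_day expects records from a single calendar date")
  hr_minutes <- sum(!is.na(day_minutes$heart_rate))
  step_total <- sum(day_minutes$steps, na.rm = TRUE)
  list(hr_minutes = hr_minutes, step_total = step_total,
       is_valid = hr_minutes >= config$min_hr_minutes_per_day &&
         step_total >= config$min_steps_per_day)
}

#' Assign calendar days to January-1-anchored 7-day weeks
#'
#' Week `w` of a year covers days of year `7(w-1)+1 ... 7w`; 52 full weeks
#' cover days 1-364, and the 1-2 remainder days at year end belong to no
#' week (NA) and are excluded from weekly analyses.
#'
#' @param dates A `Date`/`IDate` vector.
#' @return A `data.table` with columns `year` and `week` (NA for remainder
#'   days).
#' @export
assign_week <- function(dates) {
  dates <- data.table::as.IDate(dates)
  yday <- data.table::yday(dates)
  week <- (yday - 1L) %/% 7L + 1L
  week[yday > 364L] <- NA_integer_
  data.table::data.table(year = data.table::year(dates), week = week)
}

# First calendar date of a (year, week) interval.
week_start_date <- function(year, week) {
  data.table::as.IDate(sprintf("%d-01-01", year)) + 7L * (week - 1L)
}

#' Build a participant wear calendar
#'
#' Aggregates sleep-excluded minute records into per-day wear summaries and
#' per-week validity, and flags participants with at least one valid week
#' for inclusion.
#'
#' @param minutes Minute table, sleep window already excluded (and minutes
#'   before each participant's 18th birthday already dropped).
#' @param config A [paga_config()].
#' @return Object of class `paga_wear_calendar`: a list with `days` (one row
#'   per participant-date: `hr_minutes`, `step_total`, `is_valid`, `year`,
#'   `week`), `weeks` (one row per participant-week: `valid_days`,
#'   `is_valid`), and `participants` (`n_valid_weeks`, `include`).
#' @export
build_wear_calendar <- function(minutes, config = paga_config()) {
  days <- minutes[, .(
    hr_minutes = sum(!is.na(heart_rate)),
    step_total = sum(steps, na.rm = TRUE)
  ), by = .(participant_id, date)]
  days[, is_valid := hr_minutes >= config$min_hr_minutes_per_day &
         step_total >= config$min_steps_per_day]
  wk <- assign_week(days$date)
  days[, `:=`(year = wk$year, week = wk$week)]

  weeks <- days[!is.na(week), .(valid_days = sum(is_valid)),
                by = .(participant_id, year, week)]
  weeks[, is_valid := valid_days >= config$min_valid_days_per_week]

  participants <- weeks[, .(n_valid_weeks = sum(is_valid)),
                        by = participant_id]
  # participants with days but no week-assignable data still appear
  ids <- unique(days$participant_id)
  participants <- merge(data.table::data.table(participant_id = ids),
                        participants, by = "participant_id", all.x = TRUE)
  participants[is.na(n_valid_weeks), n_valid_weeks := 0L]
  participants[, include := n_valid_weeks >= 1L]
  data.table::setorder(days, participant_id, date)
  data.table::setorder(weeks, participant_id, year, week)
  structure(list(days = days[], weeks = weeks[], participants = participants[]),
            class = "paga_wear_calendar")
}

#' @export
print.paga_wear_calendar <- function(x, ...) {
  cat(sprintf(
    "<paga_wear_calendar> %d participants (%d included), %d days (%d valid), %d weeks (%d valid)\n",
    nrow(x$participants), sum(x$participants$include),
    nrow(x$days), sum(x$days$is_valid),
    nrow(x$weeks), sum(x$weeks$is_valid)))
  invisible(x)
}
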