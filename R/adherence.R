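#' Detect sustained activity bouts in a per-minute sequence
#'
#' Scans one day's per-minute activity flags (active = moderate or vigorous
#' under one algorithm) left to right. A candidate bout opens at an active
#' minute; below-threshold minutes are absorbed while the bout's cumulative
#' interruption count stays within `bout_max_interruption` (default 2); the
#' bout closes at the last active minute before the budget would be
#' exceeded, and is kept iff its span reaches `bout_min_duration` (default
#' 10). Bouts never overlap; the first and last minute of a bout are always
#' active. Minutes removed by the sleep window (and the day boundary) break
#' adjacency, so flags must cover one contiguous in-day block.
#'
#' @param active_flags Logical vector, one element per consecutive minute.
#' @param config A [paga_config()].
#' @return `data.table` with one row per bout: `start`, `end` (1-based
#'   indices into `active_flags`), `span`, `active_minutes`,
#'   `interruption_minutes`.
#' @export
detect_bouts <- function(active_flags, config = paga_config()) {
  active_flags <- as.logical(active_flags)
  active_flags[is.na(active_flags)] <- FALSE
  m <- .bout_spans_greedy(active_flags, config$bout_min_duration,
                          config$bout_max_interruption)
  if (nrow(m) == 0L)
    return(data.table::data.table(start = integer(), end = integer(),
                                  span = integer(), active_minutes = integer(),
                                  interruption_minutes = integer()))
  span <- m[, "end"] - m[, "start"] + 1L
  act <- vapply(seq_len(nrow(m)),
                function(k) sum(active_flags[m[k, "start"]:m[k, "end"]]),
                integer(1))
  data.table::data.table(start = m[, "start"], end = m[, "end"], span = span,
                         active_minutes = act,
                         interruption_minutes = span - act)
}

# Enumeration-based reference detector (independent route; used by the
# oracle-equivalence tests, never by the pipeline).
bout_reference <- function(active_flags, config = paga_config()) {
  active_flags <- as.logical(active_flags)
  active_flags[is.na(active_flags)] <- FALSE
  .bout_spans_oracle(active_flags, config$bout_min_duration,
                     config$bout_max_interruption)
}

# Weighted MVPA minutes (moderate + vpa_weight x vigorous) inside detected
# bouts, given the day's per-minute labels for one contiguous block.
.bouted_weighted_mvpa <- function(labels, config) {
  active <- labels %in% c("moderate", "vigorous")
  if (!any(active)) return(0)
  bouts <- detect_bouts(active, config)
  if (nrow(bouts) == 0L) return(0)
  w <- numeric(length(labels))
  w[labels == "moderate"] <- 1
  w[labels == "vigorous"] <- config$vpa_weight
  sum(vapply(seq_len(nrow(bouts)),
             function(k) sum(w[bouts$start[k]:bouts$end[k]]), numeric(1)))
}

# Per-day weighted MVPA, bouted and unbouted, from one day's minute rows and
# labels. The day is laid out on its clock grid so that nonwear gaps count
# as inactive minutes and the sleep window splits the day into contiguous
# blocks scanned separately.
.day_mvpa <- function(minute_of_day, labels, config) {
  grid <- rep(factor("unclassifiable", levels = INTENSITY_LEVELS), 1440L)
  grid[minute_of_day + 1L] <- labels
  keep <- !in_sleep_window(0:1439, config)
  blocks <- split(which(keep), cumsum(!keep)[keep])
  lab_num <- as.character(grid)
  unbouted <- sum(lab_num == "moderate") + config$vpa_weight * sum(lab_num == "vigorous")
  bouted <- sum(vapply(blocks, function(idx)
    .bouted_weighted_mvpa(grid[idx], config), numeric(1)))
  c(unbouted = unbouted, bouted = bouted)
}

#' Weekly MVPA from one valid week's daily profiles
#'
#' Sums weighted MVPA (moderate + `vpa_weight` x vigorous minutes) over the
#' week's valid days and, under the default `weekly_scaling =
#' "extrapolate"`, scales to a 7-day equivalent: `7 x total / n_valid_days`.
#' With `"raw_sum"` the unscaled total is returned.
#'
#' @param daily_weighted_mvpa Numeric vector of weighted MVPA minutes, one
#'   element per valid day of the week.
#' @param config A [paga_config()].
#' @return Minutes/week (7-day equivalent by default).
#' @export
weekly_mvpa <- function(daily_weighted_mvpa, config = paga_config()) {
  n <- length(daily_weighted_mvpa)
  if (n == 0L) stop("weekly_mvpa requires at least one valid day")
  total <- sum(daily_weighted_mvpa)
  if (config$weekly_scaling == "extrapolate") 7 * total / n else total
}

#' Score guideline adherence for every included participant
#'
#' For one intensity algorithm, computes per-participant average weekly MVPA
#' (2018 rule: all MVPA minutes) and average weekly bouted MVPA (2008 rule:
#' only minutes inside qualifying bouts), averaged over the participant's
#' valid weeks, plus the 150-minute adherence flags (inclusive).
#'
#' @param minutes Sleep-excluded minute table (adult minutes only).
#' @param calendar The [build_wear_calendar()] result for `minutes`.
#' @param method One of `"step"`, `"hr"`, `"device"`.
#' @param config A [paga_config()].
#' @param birth_dates Named `IDate` vector keyed by participant id (required
#'   for the HR method).
#' @param week_filter Optional `data.table` with columns `participant_id`,
#'   `year`, `week`: restrict scoring to these valid weeks (used after
#'   age-group selection).
#' @return `data.table` of class rows: `participant_id`, `method`,
#'   `weekly_mvpa_2018`, `weekly_bouted_mvpa_2008`, `meets_2018`,
#'   `meets_2008`, `n_valid_weeks`.
#' @export
participant_adherence <- function(minutes, calendar,
                                  method = c("step", "hr", "device"),
                                  config = paga_config(), birth_dates = NULL,
                                  week_filter = NULL) {
  method <- match.arg(method)
  valid_weeks <- calendar$weeks[is.valid_col(calendar$weeks)]
  if (!is.null(week_filter))
    valid_weeks <- merge(valid_weeks, week_filter,
                         by = c("participant_id", "year", "week"))
  if (nrow(valid_weeks) == 0L)
    stop("no valid weeks to score; participants must have >= 1 valid week")

  valid_days <- calendar$days[is.valid_col(calendar$days) & !is.na(week)]
  valid_days <- merge(valid_days,
                      valid_weeks[, .(participant_id, year, week)],
                      by = c("participant_id", "year", "week"))

  mm <- merge(minutes,
              valid_days[, .(participant_id, date)],
              by = c("participant_id", "date"))
  mm[, label := label_minutes(mm, method, config, birth_dates)]

  day_tab <- mm[, {
    v <- .day_mvpa(minute_of_day, label, config)
    .(unbouted = v[["unbouted"]], bouted = v[["bouted"]])
  }, by = .(participant_id, date)]
  # valid days with zero wear-method signal still count as zero-MVPA days
  day_tab <- merge(valid_days[, .(participant_id, date, year, week)],
                   day_tab, by = c("participant_id", "date"), all.x = TRUE)
  day_tab[is.na(unbouted), unbouted := 0]
  day_tab[is.na(bouted), bouted := 0]

  week_tab <- day_tab[, .(
    mvpa = weekly_mvpa(unbouted, config),
    bouted_mvpa = weekly_mvpa(bouted, config)
  ), by = .(participant_id, year, week)]

  res <- week_tab[, .(
    weekly_mvpa_2018 = mean(mvpa),
    weekly_bouted_mvpa_2008 = mean(bouted_mvpa),
    n_valid_weeks = .N
  ), by = participant_id]
  res[, method := method]
  res[, meets_2018 := weekly_mvpa_2018 >= config$mvpa_target]
  res[, meets_2008 := weekly_bouted_mvpa_2008 >= config$mvpa_target]
  data.table::setcolorder(res, c("participant_id", "method",
                                 "weekly_mvpa_2018", "weekly_bouted_mvpa_2008",
                                 "meets_2018", "meets_2008", "n_valid_weeks"))
  res[]
}

# small helper: the `is_valid` column, tolerating data.table scoping
is.valid_col <- function(dt) dt$is_valid
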