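#' Read minute-level wearable records
#'
#' Reads a long/tidy CSV with one row per observed device-minute and returns a
#' `data.table` sorted by participant and timestamp, with a parse report
#' attached. Required columns: `person_id`, `datetime` (ISO 8601 at minute
#' resolution, naive local clock time), `steps` (non-negative integer or
#' empty), `heart_rate` (positive or empty). An optional `device_label`
#' column holds the device's own intensity output
#' (`sedentary|lightly_active|fairly_active|very_active`, or empty).
#' Minutes absent from the file are nonwear.
#'
#' Malformed timestamps and out-of-domain values (negative steps, nonpositive
#' heart rate) are dropped row-wise and counted in the report; a duplicated
#' `(person_id, datetime)` pair is an error, as is an unknown device label.
#'
#' @param path CSV file path.
#' @param config A [paga_config()].
#' @return A `data.table` with columns `participant_id`, `timestamp`
#'   (POSIXct, UTC-encoded clock time), `date` (`IDate`), `minute_of_day`
#'   (0-1439), `steps`, `heart_rate`, `device_label`; attribute
#'   `parse_report` is a list with `rows_read`, `rows_kept`, `rows_dropped`,
#'   and a named `drop_reasons` vector.
#' @export
read_minute_data <- function(path, config = paga_config()) {
  if (!file.exists(path)) stop("minute data file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "datetime"),
                          na.strings = c("", "NA"))
  required <- c("person_id", "datetime", "steps", "heart_rate")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("minute data is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"device_label" %in% names(dt)) dt[, device_label := NA_character_]
  minute_table(dt[, c(required, "device_label"), with = FALSE])
}

#' Build a validated minute table from an in-memory data frame
#'
#' Same contract as [read_minute_data()] but starting from a `data.frame`
#' (used by the simulator and in tests to avoid round-tripping through disk).
#'
#' @param df Data frame with columns `person_id`, `datetime`, `steps`,
#'   `heart_rate` and optionally `device_label`.
#' @return See [read_minute_data()].
#' @export
minute_table <- function(df) {
  dt <- data.table::as.data.table(df)
  if (!"device_label" %in% names(dt)) dt[, device_label := NA_character_]
  rows_read <- nrow(dt)
  drop <- c(malformed_timestamp = 0L, negative_steps = 0L,
            nonpositive_heart_rate = 0L)

  ts <- .parse_minute_ts(dt$datetime)
  bad_ts <- is.na(ts) & !is.na(dt$datetime)
  bad_ts <- bad_ts | is.na(dt$datetime)
  drop["malformed_timestamp"] <- sum(bad_ts)

  steps <- suppressWarnings(as.numeric(dt$steps))
  neg <- !is.na(steps) & steps < 0
  drop["negative_steps"] <- sum(neg & !bad_ts)

  hr <- suppressWarnings(as.numeric(dt$heart_rate))
  badhr <- !is.na(hr) & hr <= 0
  drop["nonpositive_heart_rate"] <- sum(badhr & !bad_ts & !neg)

  lab <- as.character(dt$device_label)
  unknown <- !is.na(lab) & !(lab %in% DEVICE_LEVELS)
  if (any(unknown))
    stop("unknown device_label value(s): ",
         paste(unique(lab[unknown]), collapse = ", "))

  keep <- !(bad_ts | neg | badhr)
  out <- data.table::data.table(
    participant_id = as.character(dt$person_id)[keep],
    timestamp = ts[keep],
    steps = as.integer(steps[keep]),
    heart_rate = hr[keep],
    device_label = lab[keep]
  )
  out[, date := data.table::as.IDate(timestamp)]
  out[, minute_of_day := as.integer((as.numeric(timestamp) %/% 60) %% 1440)]
  data.table::setorder(out, participant_id, timestamp)

  dup <- duplicated(out, by = c("participant_id", "timestamp"))
  if (any(dup)) {
    first <- out[which(dup)[1L]]
    stop(sprintf("duplicated minute record: participant '%s' at %s",
                 first$participant_id, format(first$timestamp, "%Y-%m-%d %H:%M")))
  }
  data.table::setcolorder(out, c("participant_id", "timestamp", "date",
                                 "minute_of_day", "steps", "heart_rate",
                                 "device_label"))
  data.table::setattr(out, "parse_report",
                      list(rows_read = rows_read, rows_kept = nrow(out),
                           rows_dropped = rows_read - nrow(out),
                           drop_reasons = drop))
  out[]
}

# naive local clock time, encoded in UTC so arithmetic never crosses DST;
# per-row parsing so one malformed value never poisons the batch
.parse_minute_ts <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  ts <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M", tz = "UTC"))
  bad <- is.na(ts) & !is.na(x)
  if (any(bad))
    ts[bad] <- as.POSIXct(strptime(x[bad], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  ts - (as.numeric(ts) %% 60)  # truncate to minute resolution
}

#' Read a demographics table (plus optional long BMI table)
#'
#' The demographics CSV has one row per participant with columns `person_id`,
#' `sex` (`male|female|other_or_not_specified`), `race_ethnicity`
#' (`hispanic|nh_asian_pi|nh_black|nh_white|two_or_more|other_or_not_specified`)
#' and `birth_date` (ISO date). The companion BMI CSV, if given, is long with
#' columns `person_id`, `bmi_date`, `bmi_value`; measurements are attached
#' unfiltered (outlier and window filtering happen at classification time).
#' Category vocabularies are strict: an unknown level is an error.
#'
#' @param path Demographics CSV path.
#' @param bmi_path Optional BMI measurement CSV path.
#' @return A list of class `paga_demographics` with elements `participants`
#'   (one row per person) and `bmi` (long, date-ordered, possibly empty).
#' @export
read_demographics <- function(path, bmi_path = NULL) {
  if (!file.exists(path)) stop("demographics file not found: ", path)
  demo <- data.table::fread(path, na.strings = c("", "NA"))
  bmi <- if (!is.null(bmi_path)) {
    if (!file.exists(bmi_path)) stop("BMI file not found: ", bmi_path)
    data.table::fread(bmi_path, na.strings = c("", "NA"))
  } else NULL
  demographics_table(demo, bmi)
}

#' Build a validated demographics object from in-memory tables
#'
#' @param demo Data frame with `person_id`, `sex`, `race_ethnicity`,
#'   `birth_date`.
#' @param bmi Optional long data frame with `person_id`, `bmi_date`,
#'   `bmi_value`.
#' @return See [read_demographics()].
#' @export
demographics_table <- function(demo, bmi = NULL) {
  demo <- data.table::as.data.table(demo)
  required <- c("person_id", "sex", "race_ethnicity", "birth_date")
  missing_cols <- setdiff(required, names(demo))
  if (length(missing_cols))
    stop("demographics table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_sex <- setdiff(unique(as.character(demo$sex)), SEX_LEVELS)
  if (length(bad_sex))
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_race <- setdiff(unique(as.character(demo$race_ethnicity)), RACE_LEVELS)
  if (length(bad_race))
    stop("unknown race_ethnicity value(s): ", paste(bad_race, collapse = ", "))
  participants <- data.table::data.table(
    participant_id = as.character(demo$person_id),
    sex = factor(demo$sex, levels = SEX_LEVELS),
    race_ethnicity = factor(demo$race_ethnicity, levels = RACE_LEVELS),
    birth_date = data.table::as.IDate(as.character(demo$birth_date))
  )
  if (anyNA(participants$birth_date)) stop("unparseable birth_date present")
  if (anyDuplicated(participants$participant_id))
    stop("duplicated person_id in demographics")

  if (is.null(bmi)) {
    bmi_dt <- data.table::data.table(participant_id = character(),
                                     bmi_date = data.table::as.IDate(integer(0)),
                                     bmi_value = numeric())
  } else {
    bmi <- data.table::as.data.table(bmi)
    if (!all(c("person_id", "bmi_date", "bmi_value") %in% names(bmi)))
      stop("BMI table needs columns person_id, bmi_date, bmi_value")
    bmi_dt <- data.table::data.table(
      participant_id = as.character(bmi$person_id),
      bmi_date = data.table::as.IDate(as.character(bmi$bmi_date)),
      bmi_value = as.numeric(bmi$bmi_value)
    )
    data.table::setorder(bmi_dt, participant_id, bmi_date)
  }
  structure(list(participants = participants, bmi = bmi_dt),
            class = "paga_demographics")
}

#' @export
print.paga_demographics <- function(x, ...) {
  cat(sprintf("<paga_demographics> %d participants, %d BMI measurements\n",
              nrow(x$participants), nrow(x$bmi)))
  invisible(x)
}

# Write a table as CSV, replacing suppressed numeric cells with a literal
# token. `suppress_cols` are blanked wherever `suppressed` is TRUE.
.write_suppressed_csv <- function(dt, path, suppress_cols = character()) {
  out <- data.table::copy(data.table::as.data.table(dt))
  if (length(suppress_cols) && "suppressed" %in% names(out)) {
    for (col in intersect(suppress_cols, names(out))) {
      vals <- as.character(out[[col]])
      vals[out$suppressed] <- "SUPPRESSED"
      data.table::set(out, j = col, value = vals)
    }
  }
  data.table::fwrite(out, path)
  invisible(path)
}
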