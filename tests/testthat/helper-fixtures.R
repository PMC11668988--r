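# Shared fixtures and the pure-R bout reference used across test files.

# Independent enumeration reference for bout detection, written directly
# from the scan contract: candidates open at each unconsumed active minute,
# the end is the maximal feasible active minute with interior inactive
# count within the interruption budget, candidates below the minimum span
# are passed over. Kept in plain R so it checks both the greedy and the
# enumeration C++ routes.
r_bout_oracle <- function(active, min_dur = 10L, max_int = 2L) {
  active <- as.logical(active)
  n <- length(active)
  bouts <- list()
  i <- 1L
  while (i <= n) {
    if (!active[i]) { i <- i + 1L; next }
    best <- NA_integer_
    inactive <- 0L
    for (e in i:n) {
      if (e > i && !active[e - 1L]) inactive <- inactive + 1L
      if (inactive > max_int) break
      if (active[e]) best <- e
    }
    if (!is.na(best) && best - i + 1L >= min_dur) {
      bouts[[length(bouts) + 1L]] <- c(start = i, end = best)
      i <- best + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(bouts) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  do.call(rbind, bouts)
}

in_bout_active_minutes <- function(active, spans) {
  if (nrow(spans) == 0L) return(0L)
  sum(vapply(seq_len(nrow(spans)),
             function(k) sum(active[spans[k, "start"]:spans[k, "end"]]),
             integer(1)))
}

# Minute-table builder: one participant-day laid out on the clock grid.
make_day_minutes <- function(date = "2021-01-04", id = "P1",
                             minute_of_day = 300:1379,
                             steps = 0L, heart_rate = 80,
                             device_label = NA_character_) {
  n <- length(minute_of_day)
  minute_table(data.frame(
    person_id = id,
    datetime = sprintf("%s %02d:%02d", date,
                       minute_of_day %/% 60L, minute_of_day %% 60L),
    steps = rep_len(steps, n),
    heart_rate = rep_len(heart_rate, n),
    device_label = rep_len(device_label, n)))
}

# Small cohorts are expensive enough to share across test files.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, spec) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- generate_cohort(spec)
  .cohort_cache[[key]]
}

noisefree_cohort <- function() {
  cached_cohort("noisefree",
                cohort_spec(n_participants = 10, n_weeks = 2, seed = 3,
                            noise = FALSE))
}

noisy_cohort <- function() {
  cached_cohort("noisy",
                cohort_spec(n_participants = 16, n_weeks = 3, seed = 11))
}

expand_2x2 <- function(a, b, c, d) {
  data.frame(
    exposed = factor(rep(c("yes", "yes", "no", "no"), c(a, b, c, d)),
                     levels = c("no", "yes")),
    outcome = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)))
}
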