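#' Specify a synthetic wearable cohort
#'
#' Describes the generating process for a desk-scale stand-in cohort:
#' demographic mixture, an adherence model injecting log-odds effects on the
#' probability of the habitually exercising archetype, a wear model, and a
#' mixture of activity archetypes. Each archetype schedules runs of
#' consecutive active minutes; cadence within a run is log-normal around the
#' archetype's target, heart rate is a logistic function of cadence (times
#' the age-predicted maximum) plus Gaussian noise, and device labels follow
#' the scheduled intensity with an optional run-level inflation (upgrade one
#' intensity class) and padding, emulating the generous proprietary output.
#' With `noise = FALSE` every stochastic nuisance is switched off (full
#' wear, complete signals, deterministic cadence at the target, no
#' inflation) so pipeline output can be compared exactly against the
#' recorded ground truth.
#'
#' @param n_participants Cohort size (desk-scale default 30).
#' @param start_date First calendar day (anchor a January 1 so week indices
#'   are easy to reason about; any date works).
#' @param n_weeks Number of 7-day intervals to simulate. Default 8.
#' @param seed Integer seed; fully determines the output.
#' @param noise Logical; `FALSE` gives the deterministic, noise-free world.
#' @param demographic_mix List of named probability vectors for `sex` and
#'   `race_ethnicity` (defaults follow the source cohort's margins) plus
#'   `age_range`.
#' @param adherence_model List with `intercept` (log-odds of the
#'   bout-exerciser archetype for the reference participant) and `effects`
#'   (per-factor named log-odds shifts, default: female effect ln 0.66).
#' @param wear_model List: `wear_prob` (per-day probability the device is
#'   worn), `wear_start`/`wear_end` (clock minutes), `hr_coverage`
#'   (per-minute probability the heart-rate signal is present),
#'   `ambient_lambda` (Poisson mean steps/min outside runs),
#'   `sleep_tail_minutes` (observed minutes after 23:00 on worn days,
#'   exercising the sleep-window exclusion).
#' @param archetype_mix Named probabilities for the non-exerciser archetypes
#'   (`sedentary`, `commuter`, `sporadic_mover`); renormalised per
#'   participant against the adherence model's bout-exerciser probability.
#' @param archetypes Named list of archetype parameter lists: `runs_per_day`,
#'   `run_len`, `cadence_meanlog`, `cadence_sdlog`, `class` (intended
#'   intensity of run minutes).
#' @param hr_link List: `f_rest`, `f_max`, `c_mid`, `c_scale`, `sd` for
#'   `frac = f_rest + (f_max - f_rest) * plogis((cadence - c_mid)/c_scale)`.
#' @param device_inflation Probability a run's device label is upgraded one
#'   intensity class. @param device_padding Minutes of same-label padding
#'   added on each side of a run's device labels.
#' @param bmi_model List: `mean`, `sd`, `missing_prob`, `n_lambda` for
#'   per-participant dated BMI measurements.
#' @return Object of class `paga_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 30L,
                        start_date = "2021-01-01",
                        n_weeks = 8L,
                        seed = 1L,
                        noise = TRUE,
                        demographic_mix = list(
                          sex = c(male = 0.287, female = 0.685,
                                  other_or_not_specified = 0.028),
                          race_ethnicity = c(hispanic = 0.022, nh_asian_pi = 0.031,
                                             nh_black = 0.049, nh_white = 0.797,
                                             two_or_more = 0.021,
                                             other_or_not_specified = 0.080),
                          age_range = c(18, 75)),
                        adherence_model = list(
                          intercept = stats::qlogis(0.30),
                          effects = list(sex = c(female = log(0.66)))),
                        wear_model = list(wear_prob = 0.9, wear_start = 330L,
                                          wear_end = 1350L, hr_coverage = 0.97,
                                          ambient_lambda = 3,
                                          sleep_tail_minutes = 60L),
                        archetype_mix = c(sedentary = 0.5, commuter = 0.3,
                                          sporadic_mover = 0.2),
                        archetypes = list(
                          sedentary = list(runs_per_day = 0.2, run_len = 5,
                                           cadence_meanlog = log(70),
                                           cadence_sdlog = 0.10, class = "light"),
                          commuter = list(runs_per_day = 2, run_len = 14,
                                          cadence_meanlog = log(85),
                                          cadence_sdlog = 0.08, class = "light"),
                          bout_exerciser = list(runs_per_day = 1.2, run_len = 35,
                                                cadence_meanlog = log(112),
                                                cadence_sdlog = 0.06,
                                                class = "moderate"),
                          sporadic_mover = list(runs_per_day = 25, run_len = 1,
                                                cadence_meanlog = log(108),
                                                cadence_sdlog = 0.06,
                                                class = "moderate")),
                        hr_link = list(f_rest = 0.45, f_max = 0.95, c_mid = 90,
                                       c_scale = 25, sd = 0.02),
                        device_inflation = 0.35,
                        device_padding = 5L,
                        bmi_model = list(mean = 29.4, sd = 6.7,
                                         missing_prob = 0.47, n_lambda = 2)) {
  stopifnot(n_participants >= 1, n_weeks >= 1,
            abs(sum(demographic_mix$sex) - 1) < 1e-8,
            abs(sum(demographic_mix$race_ethnicity) - 1) < 1e-8,
            wear_model$wear_prob > 0)
  spec <- list(n_participants = as.integer(n_participants),
               start_date = data.table::as.IDate(start_date),
               n_weeks = as.integer(n_weeks), seed = as.integer(seed),
               noise = isTRUE(noise), demographic_mix = demographic_mix,
               adherence_model = adherence_model, wear_model = wear_model,
               archetype_mix = archetype_mix / sum(archetype_mix),
               archetypes = archetypes, hr_link = hr_link,
               device_inflation = device_inflation,
               device_padding = as.integer(device_padding),
               bmi_model = bmi_model)
  if (!spec$noise) {
    spec$wear_model$wear_prob <- 1
    spec$wear_model$hr_coverage <- 1
    spec$device_inflation <- 0
    spec$device_padding <- 0L
    spec$hr_link$sd <- 0
    for (a in names(spec$archetypes)) spec$archetypes[[a]]$cadence_sdlog <- 0
  }
  structure(spec, class = "paga_cohort_spec")
}

.upgrade_class <- function(cls) {
  c(sedentary = "light", light = "moderate", moderate = "vigorous",
    vigorous = "vigorous")[cls]
}
.to_device <- function(cls) {
  c(sedentary = "sedentary", light = "lightly_active",
    moderate = "fairly_active", vigorous = "very_active")[cls]
}
.class_weight <- function(cls, config) {
  ifelse(cls == "moderate", 1, ifelse(cls == "vigorous", config$vpa_weight, 0))
}

#' Generate a synthetic minute-level cohort
#'
#' Draws demographics, archetypes and minute streams from a
#' [cohort_spec()], returning the exact input tables the readers accept
#' plus a ground-truth table computed from the generating schedule itself
#' (never by running the pipeline). Scheduled runs are placed with at least
#' a 3-minute gap, so under the bout rules (span >= 10, interruption budget
#' 2) a run qualifies as a bout exactly when its length reaches 10: true
#' bouted MVPA is therefore analytic in the schedule.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, writes `minutes.csv`,
#'   `demographics.csv`, `bmi.csv`, `truth_weeks.csv`,
#'   `truth_participants.csv`.
#' @param config A [paga_config()] (supplies the MVPA target and vigorous
#'   weighting used to score the truth).
#' @return List with `minutes`, `demographics`, `bmi` (reader-format
#'   `data.table`s), `truth_weeks` (per participant-week true weighted MVPA,
#'   plain and bouted), and `truth_participants` (archetype, true average
#'   weekly MVPA, true 2018/2008 flags under the step-cadence reading of the
#'   schedule).
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir = NULL,
                            config = paga_config()) {
  stopifnot(inherits(spec, "paga_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  days <- seq(spec$start_date, by = 1L, length.out = 7L * spec$n_weeks)

  sex <- sample(names(spec$demographic_mix$sex), n, TRUE,
                prob = spec$demographic_mix$sex)
  race <- sample(names(spec$demographic_mix$race_ethnicity), n, TRUE,
                 prob = spec$demographic_mix$race_ethnicity)
  age0 <- stats::runif(n, spec$demographic_mix$age_range[1],
                       spec$demographic_mix$age_range[2])
  birth <- spec$start_date - as.integer(round(age0 * 365.25))

  # archetype: bout-exerciser probability from the adherence model,
  # remaining mass split over the other archetypes
  eta <- rep(spec$adherence_model$intercept, n)
  for (f in names(spec$adherence_model$effects)) {
    eff <- spec$adherence_model$effects[[f]]
    val <- switch(f, sex = sex, race_ethnicity = race,
                  stop("unsupported effect factor: ", f))
    hit <- val %in% names(eff)
    eta[hit] <- eta[hit] + eff[val[hit]]
  }
  p_ex <- stats::plogis(eta)
  archetype <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_ex[i]) archetype[i] <- "bout_exerciser"
    else archetype[i] <- sample(names(spec$archetype_mix), 1,
                                prob = spec$archetype_mix)
  }

  wm <- spec$wear_model
  wear_len <- wm$wear_end - wm$wear_start
  minute_chunks <- vector("list", n)
  truth_chunks <- vector("list", n)

  for (i in seq_len(n)) {
    ar <- spec$archetypes[[archetype[i]]]
    worn <- if (spec$noise) stats::runif(length(days)) < wm$wear_prob
            else rep(TRUE, length(days))
    day_rows <- vector("list", sum(worn))
    truth_day <- data.table::data.table(date = days,
                                        true_mvpa = 0, true_bouted = 0)
    k <- 0L
    for (d in which(worn)) {
      k <- k + 1L
      runs <- .schedule_runs(ar, wear_len, spec$noise)
      cls <- rep("ambient", wear_len)
      run_id <- rep(0L, wear_len)
      if (nrow(runs)) for (r in seq_len(nrow(runs))) {
        idx <- runs$start[r]:runs$end[r]
        cls[idx] <- ar$class
        run_id[idx] <- r
      }
      # truth from the schedule, not from the emitted signals
      if (nrow(runs)) {
        w <- .class_weight(ar$class, config)
        lens <- runs$end - runs$start + 1L
        truth_day[date == days[d],
                  `:=`(true_mvpa = w * sum(lens),
                       true_bouted = w * sum(lens[lens >= config$bout_min_duration]))]
      }
      cadence <- if (spec$noise)
        stats::rlnorm(wear_len, ar$cadence_meanlog, ar$cadence_sdlog)
      else rep(exp(ar$cadence_meanlog), wear_len)
      amb <- cls == "ambient"
      cadence[amb] <- if (spec$noise)
        stats::rpois(sum(amb), wm$ambient_lambda) else wm$ambient_lambda

      age_d <- age_at(birth[i], days[d])
      hl <- spec$hr_link
      frac <- hl$f_rest + (hl$f_max - hl$f_rest) *
        stats::plogis((cadence - hl$c_mid) / hl$c_scale)
      if (hl$sd > 0) frac <- frac + stats::rnorm(wear_len, 0, hl$sd)
      hr <- round(pmax(35, frac * max_heart_rate(age_d, config)), 1)
      hr_present <- if (spec$noise) stats::runif(wear_len) < wm$hr_coverage
                    else rep(TRUE, wear_len)
      hr[!hr_present] <- NA_real_

      dev_cls <- cls
      dev_cls[amb] <- "sedentary"
      if (nrow(runs)) for (r in seq_len(nrow(runs))) {
        lab <- ar$class
        if (spec$device_inflation > 0 &&
            stats::runif(1) < spec$device_inflation)
          lab <- .upgrade_class(lab)
        lo <- max(1L, runs$start[r] - spec$device_padding)
        hi <- min(wear_len, runs$end[r] + spec$device_padding)
        dev_cls[lo:hi] <- lab
      }

      mods <- wm$wear_start + seq_len(wear_len) - 1L
      tail_n <- if (spec$noise) wm$sleep_tail_minutes else 0L
      if (tail_n > 0L) {
        # observed sleep-tail minutes after 23:00: low HR, zero steps
        mods <- c(mods, 1380L + seq_len(tail_n) - 1L)
        cadence <- c(cadence, rep(0, tail_n))
        hr <- c(hr, round(0.45 * max_heart_rate(age_d, config), 1) +
                  stats::rnorm(tail_n, 0, 1))
        dev_cls <- c(dev_cls, rep("sedentary", tail_n))
      }
      day_rows[[k]] <- data.table::data.table(
        person_id = ids[i],
        datetime = paste0(format(days[d]), " ",
                          sprintf("%02d:%02d", mods %/% 60L, mods %% 60L)),
        steps = as.integer(round(cadence)),
        heart_rate = hr,
        device_label = .to_device(dev_cls))
    }
    minute_chunks[[i]] <- data.table::rbindlist(day_rows)
    truth_day[, participant_id := ids[i]]
    truth_chunks[[i]] <- truth_day
  }

  minutes <- data.table::rbindlist(minute_chunks)
  truth_days <- data.table::rbindlist(truth_chunks)
  wk <- assign_week(truth_days$date)
  truth_days[, `:=`(year = wk$year, week = wk$week)]
  truth_weeks <- truth_days[!is.na(week), .(
    true_mvpa = sum(true_mvpa), true_bouted = sum(true_bouted)
  ), by = .(participant_id, year, week)]

  truth_participants <- truth_weeks[, .(
    true_weekly_mvpa = mean(true_mvpa),
    true_weekly_bouted = mean(true_bouted)
  ), by = participant_id]
  truth_participants <- merge(
    data.table::data.table(participant_id = ids, archetype = archetype),
    truth_participants, by = "participant_id", all.x = TRUE)
  truth_participants[is.na(true_weekly_mvpa),
                     `:=`(true_weekly_mvpa = 0, true_weekly_bouted = 0)]
  truth_participants[, `:=`(
    true_meets_2018 = true_weekly_mvpa >= config$mvpa_target,
    true_meets_2008 = true_weekly_bouted >= config$mvpa_target)]

  demographics <- data.table::data.table(person_id = ids, sex = sex,
                                         race_ethnicity = race,
                                         birth_date = format(birth))
  bm <- spec$bmi_model
  bmi_rows <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < bm$missing_prob) return(NULL)
    k <- 1L + stats::rpois(1, bm$n_lambda)
    data.table::data.table(
      person_id = ids[i],
      bmi_date = format(sample(days, k, replace = TRUE)),
      bmi_value = round(pmax(15, stats::rnorm(k, bm$mean, bm$sd)), 1))
  })
  bmi <- data.table::rbindlist(bmi_rows)
  if (nrow(bmi) == 0L)
    bmi <- data.table::data.table(person_id = character(),
                                  bmi_date = character(),
                                  bmi_value = numeric())

  out <- list(minutes = minutes, demographics = demographics, bmi = bmi,
              truth_weeks = truth_weeks[],
              truth_participants = truth_participants[])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(minutes, file.path(out_dir, "minutes.csv"))
    data.table::fwrite(demographics, file.path(out_dir, "demographics.csv"))
    data.table::fwrite(bmi, file.path(out_dir, "bmi.csv"))
    data.table::fwrite(out$truth_weeks, file.path(out_dir, "truth_weeks.csv"))
    data.table::fwrite(out$truth_participants,
                       file.path(out_dir, "truth_participants.csv"))
  }
  out
}

# Schedule non-overlapping runs with >= 3-minute gaps inside [1, wear_len].
.schedule_runs <- function(ar, wear_len, noise) {
  n_runs <- if (noise) stats::rpois(1, ar$runs_per_day)
            else as.integer(round(ar$runs_per_day))
  if (n_runs <= 0L)
    return(data.table::data.table(start = integer(), end = integer()))
  lens <- if (noise) pmax(1L, stats::rpois(n_runs, ar$run_len))
          else rep(as.integer(round(ar$run_len)), n_runs)
  starts <- sort(sample.int(max(1L, wear_len - max(lens)), n_runs))
  keep_s <- integer(0); keep_e <- integer(0); last_end <- -4L
  for (r in seq_len(n_runs)) {
    s <- starts[r]
    if (s <= last_end + 3L) s <- last_end + 4L
    e <- min(wear_len, s + lens[r] - 1L)
    if (s > wear_len || e < s) next
    keep_s <- c(keep_s, s); keep_e <- c(keep_e, e); last_end <- e
  }
  data.table::data.table(start = keep_s, end = keep_e)
}

#' Participant-level cohort with injected adherence effects
#'
#' The generator's fast mode: draws demographics from the same mixture as
#' [generate_cohort()] and adherence flags directly from the stated
#' logistic model, skipping minute streams entirely. Used for statistical
#' calibration (effect recovery, null p-value uniformity) where the minute
#' pipeline is irrelevant and full-scale simulation would be prohibitive.
#'
#' @param n Participants.
#' @param intercept Log-odds of adherence at reference levels.
#' @param effects Named list per factor of named log-odds shifts, e.g.
#'   `list(sex = c(female = log(0.66)))`.
#' @param seed Integer seed.
#' @param demographic_mix As in [cohort_spec()].
#' @return `data.table`: `participant_id`, `sex`, `race_ethnicity`,
#'   `meets_2018` plus the true linear predictor `eta`.
#' @export
simulate_adherence_cohort <- function(n, intercept = stats::qlogis(0.25),
                                      effects = list(sex = c(female = log(0.66))),
                                      seed = 1L,
                                      demographic_mix = cohort_spec()$demographic_mix) {
  set.seed(seed)
  sex <- factor(sample(names(demographic_mix$sex), n, TRUE,
                       prob = demographic_mix$sex), levels = SEX_LEVELS)
  race <- factor(sample(names(demographic_mix$race_ethnicity), n, TRUE,
                        prob = demographic_mix$race_ethnicity),
                 levels = RACE_LEVELS)
  eta <- rep(intercept, n)
  for (f in names(effects)) {
    val <- as.character(switch(f, sex = sex, race_ethnicity = race,
                               stop("unsupported factor: ", f)))
    eff <- effects[[f]]
    hit <- val %in% names(eff)
    eta[hit] <- eta[hit] + eff[val[hit]]
  }
  data.table::data.table(participant_id = sprintf("S%05d", seq_len(n)),
                         sex = sex, race_ethnicity = race, eta = eta,
                         meets_2018 = stats::runif(n) < stats::plogis(eta))
}
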