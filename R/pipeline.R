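#' Process a cohort end to end
#'
#' In-memory engine behind [run_pipeline()]: adult-minute filtering, sleep
#' exclusion, wear calendar, single-age-group selection, BMI classification,
#' and adherence scoring under all three intensity algorithms restricted to
#' each participant's selected valid weeks.
#'
#' @param minutes A minute table ([minute_table()] / [read_minute_data()]).
#' @param demographics A [demographics_table()] / [read_demographics()].
#' @param config A [paga_config()].
#' @return List of class `paga_cohort_result`: `adherence` (rows per
#'   participant x method), `participants` (derived factors: age_group,
#'   bmi_category, bmi_mean, n_valid_weeks), `calendar`, `attrition`.
#' @export
process_cohort <- function(minutes, demographics, config = paga_config()) {
  birth_dates <- stats::setNames(demographics$participants$birth_date,
                                 demographics$participants$participant_id)
  attr_rows <- list()
  note <- function(stage, rows_in, rows_kept, unit = "minutes") {
    attr_rows[[length(attr_rows) + 1L]] <<- data.table::data.table(
      stage = stage, unit = unit, rows_in = rows_in, rows_kept = rows_kept,
      rows_dropped = rows_in - rows_kept)
  }

  known <- minutes$participant_id %in% names(birth_dates)
  m0 <- nrow(minutes)
  minutes <- minutes[known]
  note("demographics_match", m0, nrow(minutes))

  m0 <- nrow(minutes)
  minutes <- filter_adult_minutes(minutes, birth_dates)
  note("adult_filter", m0, nrow(minutes))

  m0 <- nrow(minutes)
  minutes <- exclude_sleep_window(minutes, config)
  note("sleep_exclusion", m0, nrow(minutes))

  calendar <- build_wear_calendar(minutes, config)
  n_all <- nrow(calendar$participants)
  included <- calendar$participants[include == TRUE, participant_id]
  note("valid_week_filter", n_all, length(included), unit = "participants")
  attrition <- data.table::rbindlist(attr_rows)
  if (length(included) == 0L) {
    stop("no participant has a valid week; attrition:\n",
         paste(utils::capture.output(print(attrition)), collapse = "\n"))
  }
  minutes <- minutes[participant_id %in% included]
  calendar <- build_wear_calendar(minutes, config)

  ag <- assign_age_group(calendar, birth_dates)

  # per-participant observation window for BMI: first kept valid week start
  # to last kept valid week end
  kw <- data.table::as.data.table(ag$kept_weeks)
  kw[, start := week_start_date(year, week)]
  windows <- kw[, .(w_start = min(start), w_end = max(start) + 6L),
                by = participant_id]
  bmi_all <- demographics$bmi
  part <- merge(
    demographics$participants[participant_id %in% included],
    merge(ag$assignments, windows, by = "participant_id"),
    by = "participant_id")
  bmi_res <- lapply(seq_len(nrow(part)), function(i) {
    classify_bmi(bmi_all[participant_id == part$participant_id[i]],
                 part$w_start[i], part$w_end[i], config)
  })
  part[, bmi_category := factor(vapply(bmi_res, function(x)
    as.character(x$bmi_category), character(1)), levels = BMI_LEVELS)]
  part[, bmi_mean := vapply(bmi_res, function(x) x$bmi_mean, numeric(1))]
  part[, c("w_start", "w_end") := NULL]

  adherence <- data.table::rbindlist(lapply(METHOD_LEVELS, function(m)
    participant_adherence(minutes, calendar, m, config, birth_dates,
                          week_filter = ag$kept_weeks)))
  part <- merge(part,
                unique(adherence[, .(participant_id, n_valid_weeks)]),
                by = "participant_id")
  structure(list(adherence = adherence, participants = part[],
                 calendar = calendar, attrition = attrition),
            class = "paga_cohort_result")
}

#' @export
print.paga_cohort_result <- function(x, ...) {
  cat(sprintf("<paga_cohort_result> %d participants, %d adherence rows\n",
              nrow(x$participants), nrow(x$adherence)))
  print(x$attrition)
  invisible(x)
}

#' Aim 1-3 statistics for a processed cohort
#'
#' Builds the grouped-proportion tables (with pairwise chi-square), the
#' univariate and multivariate logistic fits for the step-method 2018
#' outcome, and the pairwise McNemar comparisons of the three algorithms'
#' 2008 adherence.
#'
#' @param result A [process_cohort()] result (or equivalent list with
#'   `adherence` and `participants`).
#' @param config A [paga_config()].
#' @return List: `group_tables`, `chisq`, `models` (terms rows stacked with
#'   a `mode` column), `mcnemar`.
#' @export
cohort_statistics <- function(result, config = paga_config()) {
  part <- data.table::as.data.table(result$participants)
  adh <- data.table::as.data.table(result$adherence)
  step18 <- adh[method == "step",
                .(participant_id, meets_2018)]
  dat <- merge(part, step18, by = "participant_id")

  factors <- c(sex = "sex", race_ethnicity = "race_ethnicity",
               bmi_category = "bmi_category", age_group = "age_group")
  references <- c(sex = "male", race_ethnicity = "nh_white",
                  bmi_category = "normal", age_group = "18-29")

  group_tables <- data.table::rbindlist(lapply(names(factors), function(f) {
    g <- group_adherence_table(dat$meets_2018, dat[[f]], config)
    g[, factor := f]
    data.table::setcolorder(g, "factor")
  }))
  chisq <- data.table::rbindlist(lapply(names(factors), function(f) {
    counts <- group_tables[factor == f & n > 0, .(level, n, n_adherent)]
    if (nrow(counts) < 2L) return(NULL)
    cs <- pairwise_chisq(counts, config)
    cs[, factor := f]
    data.table::setcolorder(cs, "factor")
  }))

  fit_one <- function(facs, mode) {
    usable <- facs[vapply(facs, function(f)
      length(unique(droplevels(as.factor(dat[[f]])))) >= 2L, logical(1))]
    if (length(usable) == 0L || length(unique(dat$meets_2018)) < 2L)
      return(NULL)
    fit <- fit_logistic(dat, "meets_2018", usable,
                        references[usable], config)
    t <- data.table::copy(fit$terms)
    t[, `:=`(mode = mode, converged = fit$converged,
             max_vif = if (length(fit$vif)) max(fit$vif) else NA_real_)]
    t
  }
  models <- data.table::rbindlist(c(
    lapply(names(factors), function(f) fit_one(f, paste0("univariate_", f))),
    list(fit_one(unname(factors), "multivariate"))), use.names = TRUE)

  wide08 <- data.table::dcast(adh, participant_id ~ method,
                              value.var = "meets_2008")
  pairs <- utils::combn(METHOD_LEVELS, 2)
  mcnemar <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r <- mcnemar_compare_methods(wide08[[a]], wide08[[b]], config)
    data.table::data.table(method_a = a, method_b = b, b_only = r$b,
                           c_only = r$c, statistic = r$statistic, p = r$p,
                           significant = r$significant)
  }))
  adopt <- adh[, .(n = .N, n_adherent_2008 = sum(meets_2008),
                   prop_2008 = mean(meets_2008),
                   n_adherent_2018 = sum(meets_2018),
                   prop_2018 = mean(meets_2018)), by = method]
  list(group_tables = group_tables[], chisq = chisq[], models = models[],
       mcnemar = mcnemar[], method_summary = adopt[])
}

#' Run the full pipeline from files to files
#'
#' Reads the minute and demographics CSVs, processes the cohort, computes
#' the cohort statistics, and writes the output tables plus a JSON run
#' manifest (effective config, seed, parse report and stage-by-stage
#' attrition). Suppressed cells in displayed tables are written as the
#' literal token `SUPPRESSED`.
#'
#' @param minute_path,demo_path,bmi_path Input CSV paths (`bmi_path`
#'   optional).
#' @param config A [paga_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list from [cohort_statistics()] plus the
#'   [process_cohort()] result; writes `adherence.csv`, `participants.csv`,
#'   `group_summary.csv`, `model_fits.csv`, `method_comparison.csv`,
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(minute_path, demo_path, bmi_path = NULL,
                         config = paga_config(), out_dir = ".") {
  minutes <- read_minute_data(minute_path, config)
  parse_report <- attr(minutes, "parse_report")
  demographics <- read_demographics(demo_path, bmi_path)
  result <- process_cohort(minutes, demographics, config)
  stats_out <- cohort_statistics(result, config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(result$adherence, file.path(out_dir, "adherence.csv"))
  data.table::fwrite(result$participants,
                     file.path(out_dir, "participants.csv"))
  .write_suppressed_csv(stats_out$group_tables,
                        file.path(out_dir, "group_summary.csv"),
                        suppress_cols = c("n_adherent", "proportion",
                                          "wald_se", "ci_low", "ci_high"))
  data.table::fwrite(stats_out$models, file.path(out_dir, "model_fits.csv"))
  mc <- data.table::copy(stats_out$mcnemar)
  data.table::fwrite(mc, file.path(out_dir, "method_comparison.csv"))

  manifest <- list(
    config = .config_as_list(config),
    seed = config$random_seed,
    parse_report = parse_report,
    attrition = result$attrition,
    n_participants_included = nrow(result$participants))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(stats_out, list(result = result)))
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$step_thresholds <- as.list(out$step_thresholds)
  out$hr_fractions <- as.list(out$hr_fractions)
  out
}
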