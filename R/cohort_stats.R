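#' Drop minute records observed before the 18th birthday
#'
#' @param minutes Minute table.
#' @param birth_dates Named `IDate` vector keyed by participant id.
#' @return Filtered minute table.
#' @export
filter_adult_minutes <- function(minutes, birth_dates) {
  bd <- birth_dates[minutes$participant_id]
  if (anyNA(bd)) stop("birth date missing for some participants in minute data")
  minutes[age_at(bd, minutes$date) >= 18L]
}

# 18th-birthday cutoff helper used by the simulator
adult_cutoff_date <- function(birth_date) {
  lt <- as.POSIXlt(data.table::as.IDate(birth_date))
  lt$year <- lt$year + 18L
  out <- data.table::as.IDate(as.Date(lt))
  # Feb 29 birthdays roll to Mar 1 in non-leap years
  bad <- is.na(out)
  if (any(bad)) out[bad] <- data.table::as.IDate(
    sprintf("%d-03-01", 1900L + lt$year[bad]))
  out
}

#' Assign each participant to a single age group
#'
#' A valid week belongs to the age group of the participant's age (completed
#' years) on the week's first day. Participants whose observation spans
#' several groups keep only the group holding the most valid weeks (ties go
#' to the older group); valid weeks outside the chosen group are dropped
#' from every downstream computation.
#'
#' @param calendar A [build_wear_calendar()] result.
#' @param birth_dates Named `IDate` vector keyed by participant id.
#' @return List with `assignments` (`participant_id`, `age_group`) and
#'   `kept_weeks` (`participant_id`, `year`, `week`) naming the valid weeks
#'   inside each participant's chosen group.
#' @export
assign_age_group <- function(calendar, birth_dates) {
  vw <- calendar$weeks[is_valid == TRUE,
                       .(participant_id, year, week)]
  if (nrow(vw) == 0L) stop("no valid weeks in calendar")
  bd <- birth_dates[vw$participant_id]
  age <- age_at(bd, week_start_date(vw$year, vw$week))
  vw[, age_group := cut_age_group(age)]
  counts <- vw[, .N, by = .(participant_id, age_group)]
  # older group wins ties: order by N then by age-group level index
  counts[, grp_idx := as.integer(age_group)]
  data.table::setorder(counts, participant_id, -N, -grp_idx)
  assignments <- counts[, .SD[1L], by = participant_id][
    , .(participant_id, age_group)]
  kept <- merge(vw, assignments, by = c("participant_id", "age_group"))[
    , .(participant_id, year, week)]
  list(assignments = assignments[], kept_weeks = kept[])
}

#' Map adult ages to the analysis age groups
#' @param age Integer ages (>= 18).
#' @return Factor over `18-29 ... 70+`.
#' @export
cut_age_group <- function(age) {
  if (any(age < 18, na.rm = TRUE)) stop("age groups are defined for adults")
  cut(age, breaks = c(18, 30, 40, 50, 60, 70, Inf), right = FALSE,
      labels = AGE_GROUP_LEVELS)
}

#' Classify BMI from dated measurements
#'
#' Averages all measurements dated within the participant's observation
#' window (first valid week start through last valid week end), after
#' discarding implausible values (outside `[12, 150]` kg/m^2). Category
#' edges are `[lower, upper)`: normal `[18.5, 25)`, overweight `[25, 30)`,
#' obese `[30, 35)`, severely obese `>= 35`. A mean below 18.5 or no usable
#' measurement yields `other_or_not_specified`.
#'
#' @param bmi_measurements `data.table` with `bmi_date`, `bmi_value` for one
#'   participant.
#' @param window_start,window_end Observation window dates (inclusive).
#' @param config A [paga_config()].
#' @return List with `bmi_category` (factor) and `bmi_mean` (NA if none).
#' @export
classify_bmi <- function(bmi_measurements, window_start, window_end,
                         config = paga_config()) {
  v <- bmi_measurements[bmi_date >= window_start & bmi_date <= window_end,
                        bmi_value]
  v <- v[!is.na(v) & v >= config$bmi_lower_outlier & v <= config$bmi_upper_outlier]
  if (length(v) == 0L)
    return(list(bmi_category = factor("other_or_not_specified", BMI_LEVELS),
                bmi_mean = NA_real_))
  m <- mean(v)
  cat <- if (m < config$bmi_underweight_cutoff) "other_or_not_specified"
         else if (m < 25) "normal"
         else if (m < 30) "overweight"
         else if (m < 35) "obese"
         else "severely_obese"
  list(bmi_category = factor(cat, BMI_LEVELS), bmi_mean = m)
}

#' Grouped adherence proportions with Wald intervals and suppression
#'
#' One row per level of a grouping factor: participants, adherent count,
#' proportion, Wald standard error and 95% CI (`p +/- 1.96 sqrt(p(1-p)/n)`,
#' truncated to `[0, 1]`). A row is flagged suppressed when either displayed
#' cell (adherent or non-adherent count) falls below the suppression
#' threshold; suppression affects display only, never computation.
#'
#' @param flags Logical adherence flags, one per participant.
#' @param groups Factor of the same length (level order preserved).
#' @param config A [paga_config()].
#' @return `data.table`: `level`, `n`, `n_adherent`, `proportion`,
#'   `wald_se`, `ci_low`, `ci_high`, `suppressed`.
#' @export
group_adherence_table <- function(flags, groups, config = paga_config()) {
  groups <- as.factor(groups)
  out <- data.table::data.table(level = levels(groups))
  out[, n := as.integer(table(groups)[level])]
  out[, n_adherent := vapply(level, function(l)
    sum(flags[groups == l]), integer(1))]
  out[, proportion := ifelse(n > 0, n_adherent / n, NA_real_)]
  out[, wald_se := sqrt(proportion * (1 - proportion) / n)]
  out[, ci_low := pmax(0, proportion - 1.96 * wald_se)]
  out[, ci_high := pmin(1, proportion + 1.96 * wald_se)]
  out[, suppressed := n == 0L | n_adherent < config$suppression_threshold |
        (n - n_adherent) < config$suppression_threshold]
  out[]
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `ad/bc` with the Wald interval
#' `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; equals the
#' exponentiated coefficient of the saturated univariate logistic
#' regression. A zero cell yields an undefined result flagged `defined =
#' FALSE` (no continuity correction).
#'
#' @param a,b Exposed adherent / non-adherent counts.
#' @param c,d Reference adherent / non-adherent counts.
#' @return List: `or`, `ci_low`, `ci_high`, `log_or`, `se`, `defined`.
#' @examples
#' odds_ratio_from_counts(1864, 7689, 1069, 2938)$or # ~0.67
#' @export
odds_ratio_from_counts <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (min(a, b, c, d) == 0)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                log_or = NA_real_, se = NA_real_, defined = FALSE))
  log_or <- log(a) - log(b) - log(c) + log(d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or), ci_low = exp(log_or - 1.96 * se),
       ci_high = exp(log_or + 1.96 * se), log_or = log_or, se = se,
       defined = TRUE)
}

#' Logistic regression of adherence on categorical factors
#'
#' Maximum-likelihood logistic fit with dummy coding against stated
#' reference levels, reporting per-term odds ratios, 95% Wald intervals and
#' two-sided Wald p-values, plus variance inflation factors computed per
#' design column from auxiliary linear regressions (`VIF_j = 1/(1-R^2_j)`).
#' Univariate mode fits one factor at a time is obtained by passing a
#' single factor name.
#'
#' @param data Data frame holding the outcome and factor columns.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param factors Character vector of factor column names.
#' @param references Named character vector of reference levels (optional;
#'   defaults to each factor's first level).
#' @param config A [paga_config()].
#' @return Object of class `paga_model_fit`: list with `terms`
#'   (`data.table`: factor, level, reference, beta, se, odds_ratio, ci_low,
#'   ci_high, wald_p, significant), `vif` (named numeric), `vif_ok`,
#'   `converged`, `n`, `model` (the `glm` object).
#' @export
fit_logistic <- function(data, outcome, factors, references = NULL,
                         config = paga_config()) {
  dt <- data.table::as.data.table(data)
  y <- as.integer(as.logical(dt[[outcome]]))
  if (anyNA(y)) stop("outcome contains missing values")
  for (f in factors) {
    v <- droplevels(as.factor(dt[[f]]))
    if (nlevels(v) < 2L) stop("factor '", f, "' has fewer than 2 levels")
    # unobserved stated reference (possible at small n): first observed
    # level stands in, and the terms table records the level actually used
    if (!is.null(references) && f %in% names(references) &&
        references[[f]] %in% levels(v))
      v <- stats::relevel(v, ref = references[[f]])
    data.table::set(dt, j = f, value = v)
  }
  dt[, .y_ := y]
  form <- stats::as.formula(paste(".y_ ~", paste(factors, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dt)

  cf <- summary(fit)$coefficients
  keep <- rownames(cf) != "(Intercept)"
  term_names <- rownames(cf)[keep]
  # map design-column names back to (factor, level)
  fac_of <- level_of <- character(length(term_names))
  for (i in seq_along(term_names)) {
    for (f in factors) {
      if (startsWith(term_names[i], f)) {
        fac_of[i] <- f
        level_of[i] <- substring(term_names[i], nchar(f) + 1L)
        break
      }
    }
  }
  beta <- cf[keep, "Estimate"]
  se <- cf[keep, "Std. Error"]
  p <- cf[keep, "Pr(>|z|)"]
  terms <- data.table::data.table(
    factor = fac_of, level = level_of,
    reference = vapply(fac_of, function(f) levels(dt[[f]])[1L], character(1)),
    beta = beta, se = se, odds_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    wald_p = p, significant = p < config$alpha_primary)

  X <- stats::model.matrix(fit)
  vif <- .design_vif(X)
  structure(list(terms = terms[], vif = vif,
                 vif_ok = length(vif) == 0L ||
                   (all(is.finite(vif)) && all(vif < 5)),
                 converged = fit$converged, n = length(y), model = fit),
            class = "paga_model_fit")
}

# VIF per non-intercept design column via auxiliary linear regressions
.design_vif <- function(X) {
  cols <- setdiff(colnames(X), "(Intercept)")
  if (length(cols) < 2L) return(stats::setNames(rep(1, length(cols)), cols))
  out <- stats::setNames(numeric(length(cols)), cols)
  for (j in cols) {
    others <- setdiff(cols, j)
    # collinear columns give an (expected) exact fit; VIF = Inf is the signal
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, others, drop = FALSE]))$r.squared)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' @export
print.paga_model_fit <- function(x, ...) {
  cat(sprintf("<paga_model_fit> n=%d, converged=%s, max VIF=%.2f\n",
              x$n, x$converged, suppressWarnings(max(x$vif))))
  print(x$terms[, .(factor, level, odds_ratio, ci_low, ci_high, wald_p)],
        digits = 3)
  invisible(x)
}

#' Pairwise chi-square tests of grouped proportions
#'
#' Pearson chi-square (1 df, no continuity correction unless configured) on
#' each 2x2 pair of levels; significance at the Bonferroni-adjusted
#' `alpha_chisq`. Pairs with a zero margin are skipped and reported.
#'
#' @param counts `data.table`/data.frame with columns `level`, `n`,
#'   `n_adherent`.
#' @param config A [paga_config()].
#' @return `data.table`: `level_a`, `level_b`, `statistic`, `p`,
#'   `significant`, `skipped`.
#' @export
pairwise_chisq <- function(counts, config = paga_config()) {
  counts <- data.table::as.data.table(counts)
  lv <- as.character(counts$level)
  pairs <- utils::combn(seq_along(lv), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tab <- matrix(c(counts$n_adherent[i], counts$n[i] - counts$n_adherent[i],
                    counts$n_adherent[j], counts$n[j] - counts$n_adherent[j]),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.table::data.table(level_a = lv[i], level_b = lv[j],
                                    statistic = NA_real_, p = NA_real_,
                                    significant = NA, skipped = TRUE))
    stat <- .pearson_chisq(tab, config$continuity_correction)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    data.table::data.table(level_a = lv[i], level_b = lv[j], statistic = stat,
                           p = p, significant = p < config$alpha_chisq,
                           skipped = FALSE)
  })
  data.table::rbindlist(res)
}

.pearson_chisq <- function(tab, correct = FALSE) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - e)
  if (correct) d <- pmax(0, d - 0.5)
  sum(d^2 / e)
}

#' Paired McNemar comparison of two adherence algorithms
#'
#' McNemar statistic `(b - c)^2 / (b + c)` on the discordant pairs of two
#' per-participant adherence flags, referred to chi-square with 1 df
#' (continuity correction off by default); significance at the
#' Bonferroni-adjusted `alpha_mcnemar`. With no discordant pairs the
#' statistic is 0 and p = 1.
#'
#' @param flags_a,flags_b Logical vectors, one element per participant,
#'   aligned.
#' @param config A [paga_config()].
#' @return List: `b` (a-only), `c` (b-only), `statistic`, `p`, `significant`.
#' @export
mcnemar_compare_methods <- function(flags_a, flags_b, config = paga_config()) {
  if (length(flags_a) != length(flags_b)) stop("flag vectors must align")
  if (anyNA(flags_a) || anyNA(flags_b)) stop("flags must be complete")
  b <- sum(flags_a & !flags_b)
  cc <- sum(!flags_a & flags_b)
  if (b + cc == 0) {
    stat <- 0; p <- 1
  } else {
    d <- abs(b - cc)
    if (config$continuity_correction) d <- max(0, d - 1)
    stat <- d^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(b = b, c = cc, statistic = stat, p = p,
       significant = p < config$alpha_mcnemar)
}
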