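Package: wearpaga
Title: Physical Activity Guideline Adherence from Minute-Level Wearable Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes minute-level wearable device records (steps, heart
    rate, device intensity labels) into physical-activity summaries: fixed
    sleep-window exclusion, valid wear-day and wear-week classification,
    intensity estimation by cadence thresholds, percent-of-maximum heart
    rate, or device labels, detection of sustained activity bouts with a
    limited interruption allowance, and scoring of adherence to the 2008
    and 2018 Physical Activity Guidelines for Americans. Includes cohort
    statistics (grouped proportions with Wald intervals, pairwise
    chi-square, univariate and multivariate logistic regression with
    variance-inflation screening, paired McNemar method comparisons, and
    small-cell suppression) and a synthetic cohort generator for testing
    the full pipeline without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
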