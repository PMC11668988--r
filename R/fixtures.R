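#' Published adherence counts by sociodemographic group
#'
#' The 2x2 contingency inputs for the univariate odds-ratio checks: for each
#' non-reference level of sex, race/ethnicity, BMI category and age group in
#' a large US wearable cohort, the participant count and 2018-guideline
#' adherent count for the level and for its reference level, together with
#' the odds ratios (and 95% CI limits) as printed at 2-decimal precision.
#' Shipped as a plain CSV under `extdata`.
#'
#' @return `data.table` with columns `factor`, `level`, `reference`, `n`,
#'   `n_adherent`, `n_ref`, `n_ref_adherent`, `printed_or`,
#'   `printed_ci_low`, `printed_ci_high`.
#' @export
reference_adherence_counts <- function() {
  path <- system.file("extdata", "adherence_2x2_counts.csv",
                      package = "wearpaga", mustWork = TRUE)
  data.table::fread(path)
}

#' Write the small deterministic worked-example fixtures
#'
#' Emits the fixture files used in worked examples and tests: the published
#' 2x2 adherence counts, the canonical activity/interruption bout patterns,
#' and a boundary wear day sitting one heart-rate minute below validity
#' (599 HR minutes, ample steps).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
generate_worked_examples <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- file.path(dir, "table_counts.csv")
  data.table::fwrite(reference_adherence_counts(), p)
  paths <- c(paths, p)

  bout_patterns <- data.table::data.table(
    name = c("ten_active", "nine_active", "split_by_two", "split_by_three",
             "scattered"),
    pattern = c(strrep("A", 10), strrep("A", 9), "AAAAAIIAAAAA", "AAAAAIIIAAAAA",
                paste(rep("A", 15), collapse = "II")),
    expected_bouts = c(1L, 0L, 1L, 0L, 0L))
  p <- file.path(dir, "bout_patterns.csv")
  data.table::fwrite(bout_patterns, p)
  paths <- c(paths, p)

  # 599 HR-bearing minutes, 10,000 steps: invalid day (HR criterion)
  mods <- 300L + seq_len(599L) - 1L
  boundary <- data.table::data.table(
    person_id = "B0001",
    datetime = sprintf("2021-01-04 %02d:%02d", mods %/% 60L, mods %% 60L),
    steps = c(rep(17L, 588L), rep(4L, 11L)),
    heart_rate = 80,
    device_label = "sedentary")
  p <- file.path(dir, "boundary_day.csv")
  data.table::fwrite(boundary, p)
  paths <- c(paths, p)
  invisible(paths)
}

# Parse "A"/"I" pattern strings into logical activity flags.
parse_bout_pattern <- function(pattern) {
  strsplit(pattern, "")[[1]] == "A"
}
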