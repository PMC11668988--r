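# wearpaga

Physical-activity guideline adherence from minute-level wearable data.

`wearpaga` is for epidemiologists and digital-health researchers working
with consumer activity-monitor exports (Fitbit-style minute streams of
steps, heart rate and a proprietary intensity label). It turns those
streams into adherence estimates for the Physical Activity Guidelines for
Americans (PAGA) and into the cohort statistics used to compare
sociodemographic groups and to compare intensity algorithms against each
other — plus a synthetic cohort generator, so the whole chain is testable
without access-restricted data.

## What it computes

1. **Wear validation.** Clock minutes in `[23:00, 05:00)` are removed as
   presumed sleep/nonwear. A *valid day* (midnight-anchored) has ≥ 600
   heart-rate-bearing minutes and ≥ 100 steps after exclusion; a *valid
   week* (7-day intervals anchored at January 1) has ≥ 3 valid days.
   Participants need ≥ 1 valid week.
2. **Intensity, three ways.** Per minute: cadence cutpoints 60/100/130
   steps·min⁻¹ (light/moderate/vigorous); %HRmax cutpoints 0.57/0.64/0.77
   with HRmax = 208 − 0.7 × age; or the device's own labels.
3. **Adherence.** Weekly weighted MVPA = MPA + 2 × VPA, extrapolated to a
   7-day equivalent from valid days. 2018 rule: weekly average ≥ 150
   minutes. 2008 rule: same target, but only MVPA inside bouts of ≥ 10
   minutes with ≤ 2 minutes of cumulative interruption counts.
4. **Cohort statistics.** Grouped proportions with Wald 95% CIs and
   small-cell suppression (< 20), pairwise chi-square (Bonferroni
   α = 0.0012), univariate/multivariate logistic regression with Wald
   tests and VIF screening, and pairwise McNemar tests between algorithms
   (Bonferroni α = 0.0008).

## Worked example

Simulate a small cohort, run the pipeline, compare the three algorithms:

```r
library(wearpaga)

spec <- cohort_spec(n_participants = 30, n_weeks = 4, seed = 42)
cc   <- generate_cohort(spec)
res  <- process_cohort(minute_table(cc$minutes),
                       demographics_table(cc$demographics, cc$bmi))
st   <- cohort_statistics(res)
st$method_summary
#>    method     n n_adherent_2008 prop_2008 n_adherent_2018 prop_2018
#> 1:   step    30               8 0.2666667              15 0.5000000
#> 2:     hr    30              10 0.3333333              22 0.7333333
#> 3: device    30              16 0.5333333              16 0.5333333
```

Under the bout-restricted 2008 rule the device algorithm reports the most
adherent participants, the heart-rate method fewer, the cadence method the
fewest (`prop_2008`: 0.53 > 0.33 > 0.27) — the generator reproduces, by
construction, the ordering observed on real multiyear Fitbit cohorts.
Per-minute primitives are exported too:

```r
detect_bouts(c(rep(TRUE, 5), FALSE, FALSE, rep(TRUE, 5)))
#>    start   end  span active_minutes interruption_minutes
#> 1:     1    12    12             10                    2

or <- odds_ratio_from_counts(1864, 9553 - 1864, 1069, 4007 - 1069)
sprintf("female vs male univariate OR %.2f (%.2f-%.2f)", or$or, or$ci_low, or$ci_high)
#> "female vs male univariate OR 0.67 (0.61-0.73)"
```

The second call reproduces a published adherence odds ratio directly from
printed group counts (see `reference_adherence_counts()` for the full
table).

## Command line

```sh
inst/exec/wearpaga simulate --out sim --n 30 --weeks 4 --seed 42
inst/exec/wearpaga process  --minutes sim/minutes.csv \
    --demographics sim/demographics.csv --bmi sim/bmi.csv --out out
inst/exec/wearpaga stats --adherence out/adherence.csv \
    --participants out/participants.csv --out out/stats
inst/exec/wearpaga compare-methods --adherence out/adherence.csv --out out/mcnemar.csv
```

`process` writes `adherence.csv`, `participants.csv`, `group_summary.csv`
(suppressed cells as the literal token `SUPPRESSED`), `model_fits.csv`,
`method_comparison.csv` and a JSON run manifest with the effective
configuration and stage-by-stage attrition.

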