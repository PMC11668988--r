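---
title: "Methods: from minute-level wearable records to guideline adherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from minute-level wearable records to guideline adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearpaga)
```

## The problem

Commercial wrist-worn activity monitors produce minute-level streams of
step counts, heart rate (HR), and a proprietary intensity label. Turning
multi-year streams of this kind into population statements — *what fraction
of a cohort meets the Physical Activity Guidelines for Americans (PAGA)?* —
requires a chain of modelling decisions: which minutes count as wear, which
days and weeks are reliable enough to score, how a minute's intensity is
inferred from each signal, and how weekly activity is summarised against the
guideline targets. `wearpaga` implements that chain as a tested pipeline,
together with the cohort-level statistics used to compare sociodemographic
groups and to compare the three intensity algorithms against each other.

The 2018 PAGA counts every minute of moderate-to-vigorous physical activity
(MVPA); adherence is a weekly average of at least 150 weighted minutes,
where a vigorous minute counts as two moderate ones
(MPA + 2×VPA ≥ 150). The 2008 edition counts only MVPA accrued in
sustained bouts of at least 10 minutes, with up to 2 minutes of
interruption tolerated per bout.

## Wear validation

Consumer devices lack sleep logs, so a fixed overnight window stands in for
sleep/nonwear: every record with clock time in `[23:00, 05:00)` is removed.
The interval is treated as half-open — the minute labelled 05:00 is kept —
because "from 11 PM to 5 AM" is ambiguous at its endpoints and a half-open
convention avoids double counting a boundary minute. Removal leaves at most
1080 observable minutes per calendar day.

A **valid wear day** is a midnight-anchored day with at least 600 minutes
bearing a heart-rate value and at least 100 total steps, both inclusive,
assessed after sleep exclusion (exclusion precedes validity in the
workflow). The two criteria are independent: a minute with HR but missing
steps counts toward the HR criterion and contributes zero steps.

A **valid week** is a 7-day interval, anchored at January 1 of each year,
containing at least 3 valid days. Fifty-two such intervals cover days
1–364; the 1–2 remainder days at year end belong to no week. A 1–2-day
"week" could never reach 3 valid days, and including it would distort
weekly averages, so it is excluded outright. Participants need at least one
valid week to enter any analysis.

## Intensity classification

Three algorithms label each wear minute as sedentary, light, moderate or
vigorous:

* **Cadence (step) method** — steps/minute against cutpoints 60 / 100 / 130
  for light / moderate / vigorous.
* **%HRmax method** — the minute's HR as a fraction of the age-predicted
  maximum (ACSM formula, `208 − 0.7 × age`), against cutpoints 0.57 / 0.64
  / 0.77. Age is in completed years on the observation date and is
  recomputed per day, so thresholds shift on birthdays.
* **Device method** — the device's own labels mapped one-to-one
  (`lightly_active` → light, `fairly_active` → moderate, `very_active` →
  vigorous).

All thresholds are inclusive at the lower edge of the higher category
(exactly 100 steps/min is moderate). The original analysis does not state
its boundary convention; inclusivity matches how the cadence literature
phrases its cutpoints ("100 steps per minute" *defines* moderate) and is
applied uniformly to avoid asymmetric boundaries. A minute lacking the
method's signal is `unclassifiable`: it contributes no intensity minutes
but still exists as wear. The three methods never share information — the
device labels cannot alter a cadence profile.

## Bout detection

The 2008 rule needs bouts. Within one day's in-wear clock grid (the sleep
window and the day boundary both break adjacency), a minute is *active* if
its label is moderate or vigorous. The detector scans left to right: a
candidate bout opens at an active minute, absorbs inactive minutes while
the bout's **cumulative** interruption count stays ≤ 2, closes at the last
active minute before the budget would be exceeded, and is kept iff its span
reaches 10 minutes. Kept bouts are consumed; a failed candidate just moves
the scan to the next active minute. Interruption minutes count toward span
but never toward MVPA — they are below threshold, and counting them would
manufacture activity.

Two readings of "interruptions of up to 2 minutes were allowed in each
bout" exist: a 2-minute cumulative budget per bout, or a 2-minute cap per
interruption *episode* (allowing several). The cumulative reading is
implemented, matching the bout definition lineage the source methodology
aligns itself with; the episodic alternative is deliberately not offered.

The detector is the package's central primitive, so it is verified against
an independent brute-force reference (maximal-feasible-window enumeration
under the same tie-breaking) exhaustively over all 2^20 binary sequences of
length 20 and over random length-200 sequences, plus a pure-R re-derivation
on smaller grids. Nonwear gaps inside a day are treated as inactive minutes
— they can be absorbed by a bout's interruption budget like any other
below-threshold minute, and there is no way to distinguish "device off for
one minute" from "stood still for one minute" in these data.

## Weekly summaries and adherence

For each valid week, weighted MVPA (moderate + 2×vigorous) is summed over
the week's **valid days** and scaled to a 7-day equivalent,
`7 × total / n_valid_days`. The source methodology never states how
3-valid-day weeks compare with 7-valid-day weeks; raw summation would
structurally penalise low-wear weeks, so extrapolation is the default and
`weekly_scaling = "raw_sum"` preserves the alternative reading. A
participant's 2018 (all MVPA) and 2008 (in-bout MVPA) scores are means over
their valid weeks; adherence is score ≥ 150, inclusive. Because bout
restriction can only remove minutes, bouted ≤ unbouted MVPA always, and
meeting the 2008 rule implies meeting the 2018 rule under the same method.

## Demographic classification

Participants are classified by sex, race/ethnicity, age group (18–29
through 70+) and BMI. Minutes before the 18th birthday are dropped before
anything else. A participant whose observation spans several age groups is
assigned the group holding the most valid weeks — each valid week goes to
the group of the participant's age on the week's first day — and the other
groups' weeks are dropped everywhere downstream. Ties are broken toward the
older group; the source is silent, any deterministic rule suffices, and the
choice is documented here.

BMI is the mean of measurements dated between the first and last kept valid
week, after discarding implausible values (< 12 or > 150 kg/m²). Category
edges are `[lower, upper)`: normal [18.5, 25), overweight [25, 30), obese
[30, 35), severely obese ≥ 35, mirroring the printed ranges
("25.0–29.9", "30–34.9", "≥35"). A mean under 18.5, or no usable
measurement, is pooled with "other or not specified" (the underweight group
is too small to display under the source's dissemination policy).

## Cohort statistics

* Grouped adherence proportions carry Wald 95% intervals,
  `p ± 1.96√(p(1−p)/n)`, truncated to [0, 1]. Any displayed cell with
  fewer than 20 participants is suppressed — at display time only, with the
  literal token `SUPPRESSED`; computation always uses full counts.
* Pairwise differences in proportions use Pearson chi-square without
  continuity correction at a Bonferroni-adjusted α = 0.0012.
* Odds ratios come from univariate and multivariate logistic regression
  with dummy coding against stated references (male, non-Hispanic White,
  normal BMI, 18–29). Wald 95% CIs and two-sided Wald p-values are
  reported per coefficient; the univariate fit on a 2×2 design equals the
  closed-form cross-product OR `ad/bc`, which the tests enforce to 1e-6
  relative error. Collinearity is screened with VIFs computed per design
  column from auxiliary linear regressions (`VIF = 1/(1−R²)`), flagged at
  5. Zero cells yield an undefined OR with an explicit flag — no silent
  continuity correction (the correction is switchable in the config).
* Method agreement uses McNemar's `(b−c)²/(b+c)` on discordant pairs, 1 df,
  no continuity correction, at Bonferroni-adjusted α = 0.0008.

The published group summaries report some proportion SEs that the simple
binomial formula does not reproduce (e.g. an overall 21.6% with SE 0.4%);
the computation behind those SEs is unstated, so the plain Wald SE is
implemented and the discrepancy is simply noted.

## The synthetic cohort generator

The real dataset behind this design (multi-year Fitbit streams for ~14,000
US adults) is access-restricted, so the package ships a generator that
emulates its *structure*: long minute-level CSVs with sleep periods,
nonwear gaps, participants who age across group boundaries mid-study, and
heterogeneous activity archetypes. It makes no attempt to match the real
cohort's demographic margins or absolute adherence percentages — only
structural and ordinal properties are targeted, and a green test on
synthetic data establishes correctness of the *processing*, not real-world
prevalence.

Each participant draws an archetype: `sedentary` (rare short strolls),
`commuter` (two ~14-minute walks/day at ~85 steps/min — light by cadence),
`bout_exerciser` (a ~35-minute session/day at ~112 steps/min — sustained
moderate), or `sporadic_mover` (many isolated moderate minutes, never a
10-minute run — the archetype that separates the 2008 and 2018 rules). The
probability of the bout-exerciser archetype follows a logistic model with
stated log-odds effects (default: a female effect of ln 0.66), which is how
demographic adherence effects are injected. Cadence within a scheduled run
is log-normal around the archetype target; HR is a logistic function of
cadence (rest fraction 0.45 rising to 0.95 around 90 steps/min) plus
Gaussian noise, making the step and HR methods correlated but not
identical — the HR link crosses the moderate threshold near 80 steps/min,
below the 100-steps/min cadence cutpoint, reproducing the real-world
pattern that HR-based estimates exceed step-based ones. Device labels
follow the scheduled intensity but can be inflated one class per run and
padded a few minutes on each side, emulating the documented generosity of
proprietary outputs; with inflation on, 2008 adherence orders device > HR >
step, the ordering reported for the real cohort.

Ground truth (true weekly MVPA, true adherence flags) is computed from the
generating schedule itself, never by running the pipeline — runs are placed
with ≥3-minute gaps so a scheduled run is a bout exactly when it is ≥10
minutes long, keeping the truth analytic. With `noise = FALSE` every
nuisance is switched off and pipeline output must (and does, in the tests)
match the truth exactly; with noise on, recovery is statistical.

Desk-scale defaults (30 participants, 8 January-anchored weeks) reflect
what a laptop can process in seconds; the real study's scale (≈1.6 million
person-weeks) is out of reach by design. Statistical calibration checks
(effect recovery at n = 10,000 across 20 seeds; null p-value uniformity at
2,000 replicates) therefore run on the generator's participant-level mode,
which draws adherence flags directly from the stated logistic model —
minute streams are irrelevant to those properties and full-scale simulation
would be prohibitive.

## Numerical and degenerate-input choices

* Timestamps are naive local clock time (encoded in UTC internally); the
  sleep window is defined on the clock, so no timezone arithmetic is
  wanted. DST transitions therefore never create 23- or 25-hour days.
* Duplicate participant-minutes are a hard error naming the offender;
  malformed timestamps, negative steps and nonpositive HR are dropped
  row-wise and itemised in the parse report.
* Unknown category levels (sex, race, device label) are hard errors:
  silent coercion of vocabulary is how cohort tables go quietly wrong.
* A cohort in which no participant attains a valid week fails with the
  stage-by-stage attrition table in the error message.
* Empty group levels yield suppressed zero rows, not errors; zero-margin
  chi-square pairs are skipped and reported; zero discordance gives a
  McNemar p of 1.

## Known limitations

* The fixed 23:00–05:00 window misclassifies shift workers' activity as
  sleep and their sleep as (non)wear; the source design shares this limit.
* `unclassifiable` minutes make the three methods' denominators subtly
  different in noisy data; profiles always account for every wear minute,
  so nothing is silently lost, but cross-method comparisons are of
  classifications, not of a shared classifiable subset.
* The generator's HR link is a convenient monotone model, not a
  physiological one; it supports ordinal claims (method ordering,
  correlation) and nothing stronger.
* Suppression is applied at the reporting boundary. Re-deriving suppressed
  cells from unsuppressed margins is possible in principle on small tables;
  guarding against complementary disclosure is out of scope.
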