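---
title: "Meal timing relative to the sleep/wake cycle: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal timing relative to the sleep/wake cycle: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronomeal)
library(dplyr)
```

## The problem

Observational chrononutrition asks whether *when* people eat — not just what
or how much — relates to cardiometabolic health. Clock time alone is a poor
reference because circadian phase differs between people; a pragmatic proxy
is to reference intake times to the sleep/wake cycle, summarized by the
midsleep point. `chronomeal` implements that analysis end to end for the
typical study design in young adults: three non-consecutive 24-h dietary
recalls (two working days, one non-working day) plus seven consecutive
nights of wrist actigraphy, followed by sex-stratified regressions of
meal-timing exposures on cardiometabolic outcomes.

The five meal-timing exposures are:

* **eating window** — hours between the first and last caloric intake of a
  day;
* **caloric midpoint** — local time at which the running total of the day's
  energy first reaches 50%;
* **eating jetlag** — non-working minus working eating *midpoint* (the
  temporal middle of the window);
* **time from midsleep point to first intake**;
* **time from last intake to midsleep point**.

## Time axes

Clock arithmetic fails across midnight, so two linearized axes are used:

* **noon-anchored axis** `[12, 36)` for sleep: onset 01:13 becomes 25.217.
  Onsets, offsets and midsleep points are averaged on this axis and mapped
  back to the clock for reporting. The nightly midsleep point is
  `onset + duration/2`.
* **within-day axis** for eating: events before 04:00 belong to the
  previous evening (00:30 becomes 24.5). The 04:00 boundary is the common
  chrononutrition convention; it is configurable (`day_start`) because the
  source protocols rarely state it.

With these conventions the per-day identity

```
(first - midsleep) + (last - first) + (midsleep' - last) = 24 h
```

holds exactly whenever the three intervals are computed against a shared
midsleep value, and approximately (we require 24 ± 0.5 h on synthetic
cohorts) when each term is a weekly mean — the published descriptive values
compose to 4.87 + 12.10 + 7.05 = 24.02 h, which is the same check at the
study's scale.

## Weekly aggregation

Recall days and actigraphy nights do not overlap by design, so the
midsleep-anchored intervals are differences of **weekly means**, not
day-matched pairs. Weekly means weight the working stratum 5/7 and the
non-working stratum 2/7. The weighting is configurable; observed-day-count
weighting is a defensible alternative, but 5/2 is the natural reading of a
"weighted mean" over a standard week and treats every participant equally.

## Input hygiene

Two rules guard data quality:

* **actigraphy validity** — a participant is excluded when wear time was
  below 16 h/day on more than 4 of the 7 days, or when no weekend
  (non-working) day was recorded;
* **dual-entry reconciliation** — each recall is entered independently by
  two dieticians; if the coefficient of variation between their daily
  energy totals (sample SD convention, `100·sd/mean`) exceeds 5%, a third
  entry is required and the best-agreeing pair is averaged event-wise, ties
  preferring the re-entered data. The CV is computed on the daily energy
  total; the underlying protocols do not state the exact quantity, and
  daily energy is the standard dietetics choice. Averaging requires equal
  event counts; mismatched entries fail loudly rather than being silently
  aligned.

Breakfast status uses a documented convention, since "breakfast" is almost
never defined in the field: a qualifying breakfast is a caloric event of at
least 50 kcal no later than 11:00 (both configurable); an event labelled
`breakfast` qualifies regardless. A participant is a *consumer* only if all
three recall days qualify.

A "caloric" event is any event with energy above 0 kcal by default
(`caloric_threshold`); some groups use 5 kcal, and the flag is retained on
non-caloric rows rather than dropping them.

## Cardiometabolic markers

* mean blood pressure `DBP + (SBP − DBP)/3`, from the average of three
  visit readings;
* `HOMA-IR = glucose × insulin / 405` (mg/dl, µIU/ml);
* LDL-C by the Friedewald equation, invalid at triglycerides ≥ 400 mg/dl
  (flagged, not imputed);
* BMI and lean-mass index as `kg/m²`.

The **composite cardiometabolic risk score** standardizes waist
circumference, blood pressure, glucose, HDL-C and triglycerides within each
sex stratum (sample SD, n − 1), flips the HDL-C z-value, and averages the
five. Within-stratum means are therefore exactly 0. The SD of the score,
however, is *below* 1 whenever the five components are imperfectly
correlated; a `restandardize` switch restores unit SD but is **off** by
default, and no test asserts SD = 1. Blood pressure enters as mean BP by
default (`bp_component = "sbp"` switches). Missing components give a
missing score; no prorating or imputation.

## Statistical layer

Triglycerides, total cholesterol, HDL-C, LDL-C and HOMA-IR are
log10-transformed; mean BP and the risk score are analyzed untransformed.
Simple regressions report the adjusted R², the standardized slope
(`b·SD(x)/SD(y)`, equal to Pearson's r for one predictor) and the slope's
two-sided p. Adjusted models add sex (pooled stratum only), Mediterranean
diet score, light physical activity, a sleep covariate and BMI. The sleep
covariate is the midsleep point for clock-time exposures and sleep
*duration* for midsleep-anchored exposures — adjusting `msp_to_first` for
the midsleep point would condition an exposure on its own ingredient. An
outcome is never included in its own covariate set (the BMI row of the body
table). Sex comparisons use classic one-way ANOVA (two groups: F = pooled
t²); breakfast-group comparisons use Welch's t.

Multiplicity is controlled within each stratum's exposure × outcome family,
separately for unadjusted and adjusted fits. Benjamini–Hochberg is the
default and Hochberg's familywise procedure is available
(`multiplicity = "hochberg"`): field practice cites both, and the choice is
deliberately a one-flag config. The family definition is itself a
convention — nothing in common reporting practice pins down whether the
family spans strata or tables — so it is documented rather than hidden.
Note that step-up-adjusted p-values are *not* fixed points of
re-adjustment; the property the package guarantees is monotonicity
(adjusted ≥ raw, non-decreasing in sorted order, capped at 1).

Every complete-case decision is per exposure–outcome pair, which is why the
reported `n` varies row by row.

## The synthetic cohort

No participant-level data from studies of this design are public, so the
generator is first-class, tested code: it is the package's test surface and
the source of its parameter-recovery guarantees.

Each participant draws latent weekly values: midsleep point
(05:04 ± 1.08 h), sleep duration (7.85 ± 1.2 h), social jetlag
(1.42 ± 0.8 h), eating window (12.10 ± 1.5 h), midsleep-to-first-intake
(4.87 ± 1.40 h) and eating jetlag (1.2 ± 0.8 h). Nights and recall days add
Gaussian jitter (0.4 h SD). Days carry breakfast, a morning snack
(~2 h later), lunch near the window midpoint, an optional evening snack and
dinner, with energies around 400/150/700/150/600 kcal — totals near
2000 kcal and a caloric midpoint near 16:00. Stratum shifts are arranged so
the 5/7–2/7 weekly means equal the latent values. Breakfast skipping
(probability 0.3) deletes the first event of one random recall day; the
window and first-intake latents are offset by the expected jump
(`skip_prob × snack_delta / 3`) so realized weekly marginals still hit
their targets. Means and SDs without a published value (jitters, jetlag
heterogeneity, meal energies, wear time, skip probability, covariate
scales) are free parameters chosen once as field-realistic defaults and
documented here — they are not claimed to match any particular study.

**Planting effects.** The men-stratum standardized slopes of log10 HOMA-IR
on eating window (−0.605) and on midsleep-to-first-intake (+0.485) are
simple-regression slopes, so the generator computes the *derived* weekly
exposures with the package's own metric functions, standardizes them within
stratum, and solves the 2 × 2 system `a = R⁻¹τ` (R the sample exposure
correlation) so each simple regression recovers its planted value despite
the exposures' slight negative correlation through shared first-intake
jitter. The residual noise is orthogonalized against both exposures and
standardized, making recovery exact in-sample rather than up to sampling
noise; strata smaller than 10 fall back to direct planting. Women's slopes
are zero. HOMA-IR is generated on the log10 scale (matching the analysis
model) and exponentiated for storage; insulin is back-derived as
`HOMA × 405 / glucose` so the HOMA identity holds exactly.

What the generator does **not** emulate: correlations among anthropometry
(weight and height are drawn independently, so synthetic BMI is wider than
real BMI), nutrient composition, seasonal or weekday structure beyond the
working/non-working dichotomy, wear-time failure modes (all synthetic
participants pass the validity filter unless sabotaged in tests), and any
effect on outcomes other than HOMA-IR. Passing recovery tests therefore
demonstrates pipeline correctness, not biological realism.

Dual data entry is emulated by scaling a copy of each day's energies so the
realized CV follows a half-normal with configurable SD (3% default);
days exceeding 5% receive a third, low-noise entry.

## Numerical choices and degenerate inputs

* All SDs are sample SDs (n − 1).
* All generator randomness flows through one seed
  (`withr::with_seed`, the idiomatic R equivalent of a local generator);
  identical configs are byte-identical on disk.
* Clock times serialize as `"HH:MM"` alongside decimal hours; reading back
  is lossless because generated events are kept within one within-day span.
* Zero-variance exposures or outcomes, strata with fewer than 2 complete
  rows, rank-deficient designs, CV of two zero totals, mismatched
  dual-entry event counts, and fewer than 3 recall days for breakfast
  classification are all loud, classed errors rather than silent NAs.
* A first intake *before* the midsleep point yields an interval near 24 h
  instead of a negative number — kept as-is as a quality-control signal.
* The normality gate for descriptive reporting is Shapiro–Wilk p ≥ 0.05 on
  the pooled sample (evenly spaced order statistics above n = 5000, where
  the test is undefined).

## Problem sizes

The test suite exercises recovery at 700 participants (a single seed,
exact-planting makes this tight) and the acceptance script at the package's
reference setting: 20 seeds × 4000 participants (2000 per sex), plus a
1000-replicate null calibration at n = 100 — sizes chosen so the whole
validation runs in minutes on a laptop while leaving Monte-Carlo error well
below the tolerances asserted.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulate = cohort_config(n_participants = 200, seed = 42),
  out_dir = "chronomeal_out")
report <- run_pipeline(cfg)
report
subset(report$tables$cardio,
       stratum == "man" & outcome == "homa_ir" & adjusted_for == "")
```

## Limitations

Sleep onset/offset are *inputs*: raw accelerometry processing, nap
handling and physical-activity intensity classification are upstream of
this package. Diet quality indices are consumed as pre-computed covariate
columns. The association layer is deliberately plain OLS — no mixed models,
no causal adjustment sets beyond the documented confounder list.
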