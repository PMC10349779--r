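# chronomeal

Chrononutrition analysis referenced to the sleep/wake cycle: from raw 24-h
dietary recall events and actigraphy-derived sleep nights to sex-stratified
associations between meal timing and cardiometabolic risk.

## What it computes

For cohorts with the standard design — three non-consecutive 24-h recalls
(two working days, one non-working) and seven consecutive actigraphy nights
per participant — the package derives:

* **Meal-timing exposures**: daily eating window (first to last caloric
  intake), caloric midpoint (time at which cumulative energy first reaches
  ≥ 50% of the daily total), eating jetlag (non-working − working eating
  midpoint), and the two circadian-referenced intervals *midsleep point →
  first intake* and *last intake → midsleep point*, all aggregated to weekly
  values with 5/7–2/7 working/non-working weights. Midsleep is
  `onset + duration/2`, averaged on a noon-anchored axis so nothing breaks
  across midnight; social jetlag is the non-working − working midsleep
  difference.
* **Input hygiene**: the 16 h-wear / ≥ 1-weekend-day actigraphy validity
  filter, and the dual-entry rule for recalls (two independent dietician
  entries; coefficient of variation of daily energy > 5% triggers a third
  entry, and the best-agreeing pair is averaged).
* **Cardiometabolic markers**: BMI, lean-mass index, mean blood pressure
  `DBP + (SBP−DBP)/3`, `HOMA-IR = glucose·insulin/405`, Friedewald LDL-C,
  and a sex-stratified composite risk Z-score (waist, blood pressure,
  glucose, HDL-C sign-flipped, triglycerides; mean of the five z-values).
* **The association layer**: log10 transforms of the skewed outcomes,
  simple and confounder-adjusted OLS with standardized β
  (= Pearson r in the simple case) and adjusted R², Welch's t, one-way
  ANOVA sex comparisons, and Benjamini–Hochberg or Hochberg multiplicity
  control over each stratum's exposure × outcome family.
* **A synthetic cohort generator** with planted, male-only standardized
  effects of eating window (−0.605) and midsleep-to-first-intake (+0.485)
  on log10 HOMA-IR, used to validate the whole pipeline by parameter
  recovery.

See `vignettes/chrononutrition-methods.Rmd` for the model, conventions and
their rationale.

## Worked example

```r
library(chronomeal)

cfg <- pipeline_config(
  simulate = cohort_config(n_participants = 200, seed = 42),
  out_dir = "chronomeal_out")
report <- run_pipeline(cfg)
report
#> chronomeal run report (v0.1.0)
#>   participants in:             200
#>   valid actigraphy:            200
#>   excluded (actigraphy rule):  0
#>   outputs:
#>      chronomeal_out/table1_descriptive.csv
#>      chronomeal_out/table2_body_composition.csv
#>      ...

subset(report$tables$cardio,
       stratum == "man" & outcome == "homa_ir" & adjusted_for == "")
#>           exposure  n   adj_r2 beta_std        p    p_adj
#>      eating_window 61  0.35528 -0.60500 2.41e-07 8.44e-06
#>   caloric_midpoint 61  0.02621  0.20600 1.11e-01 5.56e-01
#>  eating_jetlag_abs 61 -0.00105 -0.12503 3.37e-01 7.86e-01
#>       msp_to_first 61  0.22226  0.48500 7.45e-05 1.30e-03
#>        last_to_msp 61 -0.01688  0.00808 9.51e-01 9.79e-01
```

The men's stratum recovers the planted standardized slopes exactly
(−0.605 for the eating window, +0.485 for the midsleep-to-first-intake
interval, both surviving Benjamini–Hochberg adjustment), while the
unplanted exposures hover near zero — the same pattern the method is built
to detect in real cohorts: in these data a *longer* eating window and an
*earlier* first intake relative to midsleep go with lower insulin
resistance in men.

The same run on file inputs:

```r
run_pipeline(pipeline_config(recalls = "recalls.csv", sleep = "sleep.csv",
                             participants = "participants.csv",
                             out_dir = "out"))
```

or from a shell via the thin CLI:

```sh
exec/chronomeal simulate --n 200 --seed 42 --out inputs/
exec/chronomeal run --recalls inputs/recalls.csv --sleep inputs/sleep.csv \
    --participants inputs/participants.csv --out results/
```

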