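#' Pipeline configuration
#'
#' Either point the pipeline at the three input CSVs (`recalls`, `sleep`,
#' `participants`) or ask it to simulate them with a [cohort_config()];
#' exactly one of the two must be supplied. The `conventions` block collects
#' every documented analysis convention in one place.
#'
#' @param recalls,sleep,participants Input CSV paths.
#' @param simulate A [cohort_config()] to generate inputs instead.
#' @param out_dir Output directory for the report CSVs.
#' @param week_weights Working/non-working week weights.
#' @param breakfast_cutoff,breakfast_min_kcal Breakfast classification rule.
#' @param caloric_threshold Energy (kcal) above which an event is caloric.
#' @param day_start Within-day axis boundary (hours).
#' @param multiplicity `"benjamini_hochberg"` or `"hochberg"`.
#' @param bp_component Blood-pressure column entering the risk score.
#' @param restandardize_risk Re-scale the composite risk score to SD 1.
#' @param adjusted Also fit the confounder-adjusted regressions.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(recalls = NULL, sleep = NULL, participants = NULL,
                            simulate = NULL, out_dir = tempfile("chronomeal"),
                            week_weights = c(5, 2), breakfast_cutoff = 11,
                            breakfast_min_kcal = 50, caloric_threshold = 0,
                            day_start = 4,
                            multiplicity = "benjamini_hochberg",
                            bp_component = "mean_bp",
                            restandardize_risk = FALSE, adjusted = TRUE) {
  paths <- list(recalls = recalls, sleep = sleep, participants = participants)
  have_paths <- !vapply(paths, is.null, logical(1))
  if (!is.null(simulate) && any(have_paths)) {
    stop_field("simulate", "supply input paths or a simulate block, not both")
  }
  if (is.null(simulate) && !all(have_paths)) {
    stop_field("recalls",
               "all three input paths are required unless simulating")
  }
  if (!is.null(simulate) && !inherits(simulate, "cohort_config")) {
    stop_field("simulate", "must be a cohort_config()")
  }
  structure(list(
    paths = paths, simulate = simulate, out_dir = out_dir,
    conventions = list(
      week_weights = week_weights, breakfast_cutoff = breakfast_cutoff,
      breakfast_min_kcal = breakfast_min_kcal,
      caloric_threshold = caloric_threshold, day_start = day_start,
      multiplicity = multiplicity, bp_component = bp_component,
      restandardize_risk = restandardize_risk, adjusted = adjusted
    )
  ), class = "pipeline_config")
}

meal_timing_exposures <- c("eating_window", "caloric_midpoint",
                           "eating_jetlag_abs", "msp_to_first", "last_to_msp")
body_outcomes <- c("bmi", "lean_mass_index", "waist")
cardio_outcomes <- c("mean_bp", "triglycerides", "total_chol", "hdl", "ldl",
                     "homa_ir", "risk_z")

#' Assemble the per-participant analysis dataset
#'
#' Joins the weekly chrononutrition profile, the weekly sleep summary and
#' the derived biomarker panel into one row per participant, keeping the
#' exclusion bookkeeping (`valid` actigraphy flag and reason).
#'
#' @param recall_events Meal-event tibble ([read_recall_table()]).
#' @param sleep_nights Sleep-night tibble ([read_sleep_table()]).
#' @param participants Participant tibble ([read_participant_table()]).
#' @param conventions Conventions block of a [pipeline_config()].
#' @return The analysis tibble (untransformed outcomes).
#' @export
build_analysis_data <- function(recall_events, sleep_nights, participants,
                                conventions = pipeline_config(
                                  simulate = cohort_config())$conventions) {
  cv <- conventions
  recall_days <- build_recall_days(recall_events)
  sleep_summary <- weekly_sleep_summary(sleep_nights,
                                        weights = cv$week_weights)
  profile <- weekly_chrono_profile(recall_days, sleep_summary,
                                   weights = cv$week_weights,
                                   breakfast_cutoff = cv$breakfast_cutoff,
                                   breakfast_min_kcal = cv$breakfast_min_kcal)
  panel <- build_biomarker_panel(participants,
                                 bp_component = cv$bp_component,
                                 restandardize_risk = cv$restandardize_risk)
  panel |>
    left_join(profile, by = "participant_id") |>
    left_join(sleep_summary, by = "participant_id")
}

#' Descriptive (Table-1-shaped) summary
#'
#' Per-variable sample size, center and spread for all participants and per
#' sex: mean (SD) when a Shapiro-Wilk test does not reject normality at
#' p >= 0.05 in the pooled sample, median (IQR) otherwise. The sex
#' comparison p-value comes from a one-way ANOVA, on log10 values for the
#' skewed biomarkers.
#'
#' @param data Analysis tibble from [build_analysis_data()].
#' @param variables Columns to summarize (numeric).
#' @param log10_vars Variables compared between sexes on the log10 scale.
#' @return A tibble with one row per variable and stratum columns.
#' @export
descriptive_table <- function(data,
                              variables = intersect(
                                c("age", "height_cm", "weight_kg", "bmi",
                                  "lean_mass_index", "waist", "sbp", "dbp",
                                  "mean_bp", "triglycerides", "total_chol",
                                  "hdl", "ldl", "glucose", "insulin",
                                  "homa_ir", "risk_z", "sleep_duration_week",
                                  "midsleep_week", "social_jetlag_abs",
                                  "eating_window", "caloric_midpoint",
                                  "eating_jetlag_abs", "msp_to_first",
                                  "last_to_msp"), names(data)),
                              log10_vars = c("triglycerides", "total_chol",
                                             "hdl", "ldl", "homa_ir",
                                             "insulin")) {
  summarise_stratum <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3 || sd(x) == 0) {
      return(list(n = length(x), center = mean(x), spread = sd(x),
                  normal = TRUE))
    }
    # shapiro.test() accepts at most 5000 values; use evenly spaced order
    # statistics beyond that so the gate stays deterministic
    xs <- if (length(x) > 5000) {
      sort(x)[round(seq(1, length(x), length.out = 5000))]
    } else {
      x
    }
    normal <- shapiro.test(xs)$p.value >= 0.05
    if (normal) {
      list(n = length(x), center = mean(x), spread = sd(x), normal = TRUE)
    } else {
      list(n = length(x), center = median(x),
           spread = unname(diff(quantile(x, c(0.25, 0.75)))), normal = FALSE)
    }
  }
  rows <- map(variables, function(v) {
    x <- data[[v]]
    all_s <- summarise_stratum(x)
    man_s <- summarise_stratum(x[data$sex == "man"])
    woman_s <- summarise_stratum(x[data$sex == "woman"])
    cmp <- if (v %in% log10_vars) log10(replace(x, !is.na(x) & x <= 0, NA)) else x
    p_sex <- tryCatch(sex_comparison_anova(cmp, data$sex)$p,
                      error = function(e) NA_real_)
    tibble(
      variable = v, distribution = ifelse(all_s$normal, "mean (SD)",
                                          "median (IQR)"),
      n_all = all_s$n, center_all = all_s$center, spread_all = all_s$spread,
      n_man = man_s$n, center_man = man_s$center, spread_man = man_s$spread,
      n_woman = woman_s$n, center_woman = woman_s$center,
      spread_woman = woman_s$spread,
      p_sex = p_sex
    )
  })
  bind_rows(rows)
}

#' Run the full pipeline
#'
#' Reads (or simulates) the three input tables, applies the dual-entry
#' reconciliation and the actigraphy validity filter, derives the weekly
#' chrononutrition profile and the biomarker panel, and writes the
#' descriptive table, both association tables (body composition and
#' cardiometabolic outcomes) in long and wide form, and a run report with
#' the exclusion accounting.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: participant counts along the exclusion
#'   chain, output paths, the config echo and package version. The analysis
#'   tables are attached as `tables`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cv <- config$conventions
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    recall_events <- cohort$recall_events
    sleep_nights <- cohort$sleep_nights
    participants <- cohort$participants
  } else {
    recall_events <- read_recall_table(config$paths$recalls,
                                       caloric_threshold = cv$caloric_threshold,
                                       day_start = cv$day_start)
    sleep_nights <- read_sleep_table(config$paths$sleep)
    participants <- read_participant_table(config$paths$participants)
  }
  data <- build_analysis_data(recall_events, sleep_nights, participants, cv)
  no_sleep <- is.na(data$valid)
  data$valid[no_sleep] <- FALSE
  data$exclusion_reason[no_sleep] <- "no sleep nights recorded"
  n_in <- nrow(participants)
  n_sleep_valid <- sum(data$valid, na.rm = TRUE)
  analysis <- transform_outcomes(data)

  desc <- descriptive_table(data)
  assoc_body <- association_table(
    analysis, meal_timing_exposures,
    intersect(body_outcomes, names(analysis)),
    adjusted = cv$adjusted, multiplicity = cv$multiplicity)
  assoc_cardio <- association_table(
    analysis, meal_timing_exposures,
    intersect(cardio_outcomes, names(analysis)),
    adjusted = cv$adjusted, multiplicity = cv$multiplicity)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    descriptive = file.path(config$out_dir, "table1_descriptive.csv"),
    body_long = file.path(config$out_dir, "table2_body_composition.csv"),
    body_wide = file.path(config$out_dir, "table2_body_composition_wide.csv"),
    cardio_long = file.path(config$out_dir, "table3_cardiometabolic.csv"),
    cardio_wide = file.path(config$out_dir, "table3_cardiometabolic_wide.csv"),
    analysis = file.path(config$out_dir, "analysis_dataset.csv")
  )
  readr::write_csv(desc, paths["descriptive"], progress = FALSE)
  readr::write_csv(assoc_body, paths["body_long"], progress = FALSE)
  readr::write_csv(association_wide(assoc_body), paths["body_wide"],
                   progress = FALSE)
  readr::write_csv(assoc_cardio, paths["cardio_long"], progress = FALSE)
  readr::write_csv(association_wide(assoc_cardio), paths["cardio_wide"],
                   progress = FALSE)
  out_data <- data
  for (col in c("caloric_midpoint", "midsleep_week", "first_intake_week",
                "last_intake_week")) {
    if (col %in% names(out_data)) {
      out_data[[paste0(col, "_hm")]] <- format_clock_time(out_data[[col]])
    }
  }
  readr::write_csv(out_data, paths["analysis"], progress = FALSE)

  report <- structure(list(
    n_input = n_in,
    n_actigraphy_valid = n_sleep_valid,
    n_excluded_actigraphy = n_in - n_sleep_valid,
    exclusion_reasons = data |>
      filter(!.data$valid) |>
      count(.data$exclusion_reason) |>
      as.data.frame(),
    paths = paths,
    config = config,
    version = as.character(utils::packageVersion("chronomeal")),
    tables = list(descriptive = desc, body = assoc_body,
                  cardio = assoc_cardio, analysis = analysis)
  ), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("chronomeal run report (v", x$version, ")\n", sep = "")
  cat("  participants in:            ", x$n_input, "\n")
  cat("  valid actigraphy:           ", x$n_actigraphy_valid, "\n")
  cat("  excluded (actigraphy rule): ", x$n_excluded_actigraphy, "\n")
  cat("  outputs:\n")
  for (p in x$paths) cat("    ", p, "\n")
  invisible(x)
}
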