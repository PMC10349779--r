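#' Mean blood pressure
#'
#' `DBP + (SBP - DBP) / 3`, the standard one-third pulse-pressure formula,
#' in mmHg.
#'
#' @param sbp,dbp Systolic and diastolic pressure (mmHg), `sbp >= dbp > 0`.
#' @return Mean blood pressure in mmHg.
#' @examples
#' mean_blood_pressure(116.2, 70.7) # 85.9
#' @export
mean_blood_pressure <- function(sbp, dbp) {
  bad <- !is.na(sbp) & !is.na(dbp) & (sbp < dbp | dbp <= 0)
  if (any(bad)) {
    abort("systolic pressure must be >= diastolic pressure > 0",
          class = "chronomeal_input_error")
  }
  dbp + (sbp - dbp) / 3
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `glucose (mg/dl) x insulin (uIU/ml) / 405`.
#'
#' @param glucose Fasting glucose, mg/dl (> 0).
#' @param insulin Fasting insulin, uIU/ml (>= 0).
#' @return Unitless HOMA-IR index.
#' @examples
#' homa_ir(87, 7.2) # 1.547
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.na(glucose) & glucose <= 0)) {
    abort("glucose must be positive", class = "chronomeal_input_error")
  }
  if (any(!is.na(insulin) & insulin < 0)) {
    abort("insulin must be non-negative", class = "chronomeal_input_error")
  }
  glucose * insulin / 405
}

#' LDL cholesterol by the Friedewald equation
#'
#' `total cholesterol - HDL - triglycerides / 5` (mg/dl). The estimate is
#' invalid at triglycerides >= 400 mg/dl; such rows return `NA` and are
#' flagged by the caller.
#'
#' @param total_chol,hdl,triglycerides mg/dl.
#' @return Estimated LDL-C (mg/dl), `NA` where triglycerides >= 400.
#' @export
ldl_friedewald <- function(total_chol, hdl, triglycerides) {
  ifelse(!is.na(triglycerides) & triglycerides >= 400,
         NA_real_, total_chol - hdl - triglycerides / 5)
}

#' Body mass index and lean mass index
#'
#' `kg / (m)^2` with height supplied in cm.
#'
#' @param mass_kg Body (or lean) mass in kg.
#' @param height_cm Height in cm.
#' @return kg/m^2.
#' @export
mass_index <- function(mass_kg, height_cm) {
  if (any(!is.na(height_cm) & height_cm <= 0)) {
    abort("height must be positive", class = "chronomeal_input_error")
  }
  mass_kg / (height_cm / 100)^2
}

#' Sex-stratified composite cardiometabolic risk Z-score
#'
#' Standardizes waist circumference, blood pressure, glucose, HDL-C and
#' triglycerides within each sex stratum (sample SD, n - 1), flips the sign
#' of the HDL-C z-value so that all components point in the risk direction,
#' and averages the five z-values. The score is complete-case: a missing
#' component gives a missing score. Within each stratum the scores average
#' exactly zero by construction; the SD of a mean of correlated z-scores is
#' below 1 unless re-standardized, which `restandardize = TRUE` enables.
#'
#' @param panel Tibble with `sex` and the component columns `waist`,
#'   `mean_bp` (or `sbp` when `bp_component = "sbp"`), `glucose`, `hdl`,
#'   `triglycerides`.
#' @param stratify_by_sex Standardize within sex strata (default) or over
#'   the whole sample.
#' @param bp_component Which blood-pressure column enters the score.
#' @param restandardize Re-scale the final score to SD 1 within stratum.
#' @return `panel` with a `risk_z` column appended.
#' @export
risk_z_score <- function(panel, stratify_by_sex = TRUE,
                         bp_component = c("mean_bp", "sbp"),
                         restandardize = FALSE) {
  bp_component <- match.arg(bp_component)
  comp_cols <- c("waist", bp_component, "glucose", "hdl", "triglycerides")
  missing_cols <- setdiff(c(comp_cols, if (stratify_by_sex) "sex"), names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("risk score components missing from panel: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "chronomeal_schema_error")
  }
  strata <- if (stratify_by_sex) as.character(panel$sex) else rep("all", nrow(panel))
  risk <- rep(NA_real_, nrow(panel))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    comp <- as.matrix(panel[idx, comp_cols])
    complete <- complete.cases(comp)
    if (sum(complete) < 2) {
      abort(sprintf(
        "stratum \"%s\" has %d complete rows; at least 2 are required",
        s, sum(complete)), class = "chronomeal_stratum_error")
    }
    z <- scale(comp[complete, , drop = FALSE])
    if (any(attr(z, "scaled:scale") == 0)) {
      abort(sprintf("zero variance in a risk component of stratum \"%s\"", s),
            class = "chronomeal_stratum_error")
    }
    z[, "hdl"] <- -z[, "hdl"]
    score <- rowMeans(z)
    if (restandardize) score <- as.numeric(scale(score))
    risk[idx[complete]] <- score
  }
  panel$risk_z <- risk
  panel
}

#' Assemble the derived biomarker panel
#'
#' Reads the participant table columns (three-visit blood pressure readings,
#' fasting biomarkers, anthropometry) and appends the derived markers: BMI,
#' lean mass index when lean mass is supplied, visit-averaged SBP/DBP, mean
#' blood pressure, HOMA-IR, Friedewald LDL (with a `ldl_invalid` QC flag at
#' triglycerides >= 400 mg/dl) and the composite risk Z-score. Input columns
#' are never overwritten.
#'
#' @param participants Participant tibble; see [read_participant_table()]
#'   for the schema.
#' @param bp_component,restandardize_risk Passed to [risk_z_score()].
#' @return The panel tibble with derived columns appended.
#' @export
build_biomarker_panel <- function(participants,
                                  bp_component = "mean_bp",
                                  restandardize_risk = FALSE) {
  p <- as_tibble(participants)
  bp_cols <- function(prefix) {
    cols <- grep(sprintf("^%s_[0-9]+$", prefix), names(p), value = TRUE)
    if (length(cols) > 0) rowMeans(p[cols], na.rm = FALSE) else p[[prefix]]
  }
  p$sbp <- bp_cols("sbp")
  p$dbp <- bp_cols("dbp")
  p$bmi <- mass_index(p$weight_kg, p$height_cm)
  if ("lean_mass_kg" %in% names(p)) {
    p$lean_mass_index <- mass_index(p$lean_mass_kg, p$height_cm)
  }
  p$mean_bp <- mean_blood_pressure(p$sbp, p$dbp)
  p$homa_ir <- homa_ir(p$glucose, p$insulin)
  p$ldl <- ldl_friedewald(p$total_chol, p$hdl, p$triglycerides)
  p$ldl_invalid <- !is.na(p$triglycerides) & p$triglycerides >= 400
  p$waist <- p$waist_cm
  risk_z_score(p, stratify_by_sex = TRUE, bp_component = bp_component,
               restandardize = restandardize_risk)
}

#' Read a participant table
#'
#' CSV schema: `participant_id`, `sex` (`"man"`/`"woman"`), `age`,
#' `weight_kg`, `height_cm`, `waist_cm`, `sbp_1..sbp_3`, `dbp_1..dbp_3`
#' (three visit readings; single `sbp`/`dbp` columns are also accepted),
#' `glucose`, `insulin`, `triglycerides`, `total_chol`, `hdl`, and the
#' pre-computed covariates `med_diet_score` and `light_pa_min`. Optional:
#' `lean_mass_kg`.
#'
#' @param path Path to the CSV file.
#' @return A participant tibble.
#' @export
read_participant_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("participant file not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant_id", "sex", "weight_kg", "height_cm", "waist_cm",
                "glucose", "insulin", "triglycerides", "total_chol", "hdl")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("participant table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "chronomeal_schema_error")
  }
  bad_sex <- !is.na(raw$sex) & !raw$sex %in% c("man", "woman")
  if (any(bad_sex)) {
    abort_rows("sex must be \"man\" or \"woman\"", which(bad_sex))
  }
  raw$participant_id <- as.character(raw$participant_id)
  as_tibble(raw)
}
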