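#' Log10-transform the skewed cardiometabolic outcomes
#'
#' Triglycerides, total cholesterol, HDL-C, LDL-C and HOMA-IR are
#' log10-transformed before analysis; mean blood pressure and the composite
#' risk score are left untransformed. Non-positive values cannot be
#' transformed and become `NA` for that outcome (the row is flagged).
#'
#' @param panel Biomarker panel tibble.
#' @param vars Columns to transform (defaults to the five skewed markers
#'   that are present).
#' @return The panel with transformed columns and a
#'   `log10_excluded` list-column-free flag counting affected rows in
#'   attribute `n_nonpositive`.
#' @export
transform_outcomes <- function(panel,
                               vars = c("triglycerides", "total_chol", "hdl",
                                        "ldl", "homa_ir")) {
  vars <- intersect(vars, names(panel))
  n_bad <- 0L
  for (v in vars) {
    x <- panel[[v]]
    bad <- !is.na(x) & x <= 0
    n_bad <- n_bad + sum(bad)
    x[bad] <- NA_real_
    panel[[v]] <- log10(x)
  }
  structure(panel, transformed = vars, n_nonpositive = n_bad)
}

std_beta <- function(fit, x, y, term) {
  unname(coef(fit)[term] * sd(x) / sd(y))
}

#' Simple linear regression with standardized slope
#'
#' Ordinary least squares of `y` on `x`, reporting the adjusted R-squared,
#' the standardized slope (`slope x SD(x) / SD(y)`, identical to the Pearson
#' correlation for a single predictor) and the two-sided p-value of the
#' slope t-test. Complete cases only.
#'
#' @param x,y Numeric exposure and outcome vectors of equal length.
#' @param exposure,outcome,stratum Labels carried into the result row.
#' @return A one-row tibble: `exposure`, `outcome`, `stratum`, `n`,
#'   `adj_r2`, `beta_std`, `p`, `adjusted_for` (empty string).
#' @export
simple_regression <- function(x, y, exposure = "x", outcome = "y",
                              stratum = "all") {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("at least 3 complete pairs are required",
          class = "chronomeal_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y", class = "chronomeal_degenerate_error")
  }
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble(
    exposure = exposure, outcome = outcome, stratum = stratum, n = n,
    adj_r2 = s$adj.r.squared,
    beta_std = std_beta(fit, x, y, "x"),
    p = unname(s$coefficients["x", "Pr(>|t|)"]),
    adjusted_for = ""
  )
}

#' Confounder-adjusted linear regression for one exposure
#'
#' OLS of the outcome on the exposure plus a covariate matrix, reporting the
#' exposure's standardized coefficient, the model's adjusted R-squared and
#' the exposure's two-sided p-value. Complete cases only; constant
#' covariates are dropped (so an all-constant covariate set reduces exactly
#' to [simple_regression()]); any remaining rank deficiency errors out
#' naming the offending columns.
#'
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param covariates Data frame (or named list) of confounders.
#' @inheritParams simple_regression
#' @return A one-row tibble as in [simple_regression()], with
#'   `adjusted_for` listing the covariates retained.
#' @export
multiple_regression <- function(y, x, covariates, exposure = "x",
                                outcome = "y", stratum = "all") {
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  constant <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
  covariates <- covariates[, !constant, drop = FALSE]
  n <- length(x)
  if (n < ncol(covariates) + 3) {
    abort("too few complete rows for the requested adjustment",
          class = "chronomeal_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y", class = "chronomeal_degenerate_error")
  }
  dat <- cbind(data.frame(.y = y, .x = x), covariates)
  fit <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(fit)))) {
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "chronomeal_collinearity_error")
  }
  s <- summary(fit)
  tibble(
    exposure = exposure, outcome = outcome, stratum = stratum, n = n,
    adj_r2 = s$adj.r.squared,
    beta_std = std_beta(fit, x, y, ".x"),
    p = unname(s$coefficients[".x", "Pr(>|t|)"]),
    adjusted_for = paste(names(covariates), collapse = "+")
  )
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided; used for breakfast skipper vs consumer comparisons.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return A list with `statistic`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations",
          class = "chronomeal_input_error")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-way ANOVA for a sex comparison
#'
#' Classic (equal-variance) one-way analysis of variance; with two groups
#' the F statistic equals the square of the pooled-variance t statistic.
#'
#' @param values Numeric vector.
#' @param groups Group labels (at least two distinct groups).
#' @return A list with `f`, `df`, `p`.
#' @export
sex_comparison_anova <- function(values, groups) {
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(droplevels(groups)) < 2) {
    abort("at least two groups are required", class = "chronomeal_input_error")
  }
  ht <- oneway.test(values ~ groups, var.equal = TRUE)
  list(f = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Multiplicity adjustment over a declared family
#'
#' Step-up adjusted p-values: Benjamini-Hochberg false discovery rate (the
#' default; what the result tables footnote) or Hochberg familywise error
#' rate (what the methods name). Wraps [stats::p.adjust()].
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method `"benjamini_hochberg"` or `"hochberg"`.
#' @return Adjusted p-values, same length, each `>=` its input and `<= 1`.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "hochberg")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]", class = "chronomeal_input_error")
  }
  p.adjust(p, method = switch(method, benjamini_hochberg = "BH",
                              hochberg = "hochberg"))
}

# Confounder sets per the adjustment contract: clock-time exposures are
# adjusted for midsleep point; midsleep-anchored exposures for sleep
# duration (adjusting them for midsleep would condition on their own
# ingredient). Sex enters only in the pooled stratum.
confounders_for <- function(exposure, data, stratum, outcome = "") {
  sleep_cov <- if (exposure %in% c("msp_to_first", "last_to_msp")) {
    "sleep_duration_week"
  } else {
    "midsleep_week"
  }
  cols <- c(if (stratum == "all") "sex", "med_diet_score", "light_pa_min",
            sleep_cov, "bmi")
  # never adjust an outcome for itself (e.g. the BMI row of the body table)
  cols <- setdiff(intersect(cols, names(data)), outcome)
  data[, cols, drop = FALSE]
}

#' Sex-stratified association table
#'
#' Runs every exposure x outcome regression in the strata `all`, `man`,
#' `woman` (complete-case per pair, so each row carries its own `n`),
#' optionally confounder-adjusted, and applies the multiplicity adjustment
#' within each stratum's exposure-by-outcome family.
#'
#' @param data Analysis tibble: one row per participant with exposures,
#'   (transformed) outcomes, `sex` and the confounder columns.
#' @param exposures,outcomes Character vectors of column names.
#' @param adjusted Add confounder-adjusted fits (`adjusted_for` column
#'   distinguishes them).
#' @param multiplicity Passed to [adjust_pvalues()]; applied within each
#'   stratum (and adjustment layer) across the exposure x outcome grid.
#' @return A long tibble of association rows with `p_adj` and a
#'   `significant` flag (`p < 0.05`) plus `significant_adj`.
#' @export
association_table <- function(data, exposures, outcomes, adjusted = FALSE,
                              multiplicity = "benjamini_hochberg") {
  strata <- list(all = rep(TRUE, nrow(data)),
                 man = data$sex == "man",
                 woman = data$sex == "woman")
  rows <- list()
  for (st in names(strata)) {
    sub <- data[strata[[st]], , drop = FALSE]
    for (ex in exposures) {
      for (out in outcomes) {
        res <- tryCatch(
          simple_regression(sub[[ex]], sub[[out]], exposure = ex,
                            outcome = out, stratum = st),
          chronomeal_input_error = function(e) NULL,
          chronomeal_degenerate_error = function(e) NULL
        )
        rows[[length(rows) + 1]] <- res
        if (adjusted) {
          rows[[length(rows) + 1]] <- tryCatch(
            multiple_regression(sub[[out]], sub[[ex]],
                                covariates = numeric_covariates(
                                  confounders_for(ex, sub, st, out)),
                                exposure = ex, outcome = out, stratum = st),
            chronomeal_input_error = function(e) NULL,
            chronomeal_degenerate_error = function(e) NULL
          )
        }
      }
    }
  }
  res <- bind_rows(rows)
  out <- res |>
    group_by(.data$stratum, adjusted = .data$adjusted_for != "") |>
    mutate(p_adj = adjust_pvalues(.data$p, multiplicity)) |>
    ungroup() |>
    select(-"adjusted")
  out$significant <- out$p < 0.05
  out$significant_adj <- out$p_adj < 0.05
  out
}

numeric_covariates <- function(df) {
  df <- as.data.frame(df)
  for (v in names(df)) {
    if (!is.numeric(df[[v]])) df[[v]] <- as.numeric(factor(df[[v]]))
  }
  df
}

#' Reshape an association table to the wide report layout
#'
#' One row per exposure x outcome with `n`, `adj_r2`, `beta_std`, `p`
#' columns per stratum, mirroring the printed report tables.
#'
#' @param assoc Long association tibble from [association_table()]
#'   (unadjusted rows are used).
#' @return A wide tibble.
#' @export
association_wide <- function(assoc) {
  assoc |>
    filter(.data$adjusted_for == "") |>
    select("exposure", "outcome", "stratum", "n", "adj_r2", "beta_std",
           "p", "p_adj") |>
    pivot_wider(names_from = "stratum",
                values_from = c("n", "adj_r2", "beta_std", "p", "p_adj"))
}
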