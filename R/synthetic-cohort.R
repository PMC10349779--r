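#' Configuration of the synthetic cohort generator
#'
#' Bundles sample sizes, planted sex-specific effects and marginal
#' distribution parameters for [generate_cohort()]. Defaults reproduce the
#' structure of the study population the package models: 118 young adults
#' (82 women), three 24-h recalls each (two working days, one non-working),
#' seven consecutive sleep nights (five working, two weekend), and marginal
#' means/SDs taken from the published descriptive table (eating window
#' 12.10 (1.5) h, sleep duration 7.85 (1.2) h, midsleep point 05:04,
#' msp-to-first-intake 4.87 (1.40) h, ...). The planted effects are the
#' male-stratum standardized slopes of log10 HOMA-IR on the weekly eating
#' window (-0.605) and on the midsleep-to-first-intake interval (+0.485);
#' women's slopes are zero.
#'
#' @param n_participants Number of participants (>= 2 per sex stratum).
#' @param fraction_women Proportion of women, in `[0, 1]`.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param effect_beta_window_homa_men,effect_beta_msp2first_homa_men Planted
#'   standardized simple-regression slopes in the men stratum (unitless).
#' @param breakfast_skip_prob Probability that a participant skips breakfast
#'   (the first event of one random recall day is deleted).
#' @param dual_entry_cv_sd SD (percent) of the half-normal CV between the
#'   two dietician entries emitted by [emit_dual_entries()].
#' @param marginals Nested list of marginal parameters; see
#'   [cohort_marginals()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 118,
                          fraction_women = 82 / 118,
                          seed = 1,
                          effect_beta_window_homa_men = -0.605,
                          effect_beta_msp2first_homa_men = 0.485,
                          breakfast_skip_prob = 0.3,
                          dual_entry_cv_sd = 3,
                          marginals = cohort_marginals()) {
  config <- list(
    n_participants = n_participants,
    fraction_women = fraction_women,
    seed = seed,
    effect_beta_window_homa_men = effect_beta_window_homa_men,
    effect_beta_msp2first_homa_men = effect_beta_msp2first_homa_men,
    breakfast_skip_prob = breakfast_skip_prob,
    dual_entry_cv_sd = dual_entry_cv_sd,
    marginals = marginals
  )
  validate_cohort_config(config)
  structure(config, class = "cohort_config")
}

#' Marginal distribution parameters of the synthetic cohort
#'
#' Means and SDs of the sleep, meal-timing and biomarker marginals, per sex
#' where the descriptive table stratifies them. Clock-time parameters are
#' decimal hours; `midsleep_mean` is on the noon-anchored axis (29.067 =
#' 05:04). Within-person day-to-day jitter SDs are free parameters the
#' source study does not report; the defaults (0.4 h) are documented in the
#' methods vignette.
#'
#' @param sleep,meals,man,woman,covariates Named lists overriding individual
#'   entries of the corresponding default block; each marginal is
#'   `c(mean, sd)` except scalar jitter/probability entries.
#' @return A nested list of marginal parameters.
#' @export
cohort_marginals <- function(sleep = list(), meals = list(), man = list(),
                             woman = list(), covariates = list()) {
  defaults <- list(
    sleep = list(
      midsleep_mean = 29.067, midsleep_sd = 1.083,
      duration_mean = 7.85, duration_sd = 1.2,
      social_jetlag_mean = 1.42, social_jetlag_sd = 0.8,
      night_jitter_sd = 0.4,
      wear_mean = 22, wear_sd = 1
    ),
    meals = list(
      eating_window_mean = 12.10, eating_window_sd = 1.5,
      msp_to_first_mean = 4.87, msp_to_first_sd = 1.40,
      eating_jetlag_mean = 1.2, eating_jetlag_sd = 0.8,
      meal_jitter_sd = 0.4,
      morning_snack_delta = c(2, 0.5),
      evening_snack_prob = 0.6,
      kcal_breakfast = c(400, 100), kcal_lunch = c(700, 150),
      kcal_dinner = c(600, 150), kcal_snack = c(150, 50)
    ),
    man = list(
      age = c(22.5, 2.3), height = c(176.3, 6.4), weight = c(85.5, 18.5),
      lean_mass = c(53.7, 7.5), waist = c(91.4, 16.4),
      sbp = c(126.0, 12.5), dbp = c(73.0, 10.1),
      glucose = c(89.5, 10.9), log10_homa = c(0.204, 0.236),
      log10_triglycerides = c(1.869, 0.195),
      total_chol = c(157.4, 25.8), hdl = c(45.2, 8.7)
    ),
    woman = list(
      age = c(22.1, 2.1), height = c(164.5, 6.7), weight = c(65.2, 11.7),
      lean_mass = c(36.6, 5.0), waist = c(76.3, 10.9),
      sbp = c(111.8, 9.6), dbp = c(69.7, 6.6),
      glucose = c(86.0, 5.2), log10_homa = c(0.176, 0.208),
      log10_triglycerides = c(1.833, 0.175),
      total_chol = c(163.4, 30.0), hdl = c(55.0, 11.5)
    ),
    covariates = list(
      med_diet_score = c(8, 2), light_pa_min = c(120, 35),
      bp_visit_sd = 3
    )
  )
  defaults$sleep[names(sleep)] <- sleep
  defaults$meals[names(meals)] <- meals
  defaults$man[names(man)] <- man
  defaults$woman[names(woman)] <- woman
  defaults$covariates[names(covariates)] <- covariates
  defaults
}

validate_cohort_config <- function(config) {
  num1 <- function(field, lo = -Inf, hi = Inf) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      stop_field(field, sprintf("must be a single number in [%s, %s]", lo, hi))
    }
  }
  num1("n_participants", lo = 2)
  num1("fraction_women", lo = 0, hi = 1)
  num1("seed")
  num1("effect_beta_window_homa_men", lo = -1, hi = 1)
  num1("effect_beta_msp2first_homa_men", lo = -1, hi = 1)
  num1("breakfast_skip_prob", lo = 0, hi = 1)
  num1("dual_entry_cv_sd", lo = 0)
  n_women <- round(config$n_participants * config$fraction_women)
  if (n_women < 2 || config$n_participants - n_women < 2) {
    stop_field("fraction_women",
               "each sex stratum needs at least 2 participants")
  }
  for (block in names(config$marginals)) {
    for (nm in names(config$marginals[[block]])) {
      v <- config$marginals[[block]][[nm]]
      field <- paste(block, nm, sep = "$")
      if (!is.numeric(v) || anyNA(v)) stop_field(field, "must be numeric")
      if (length(v) == 2 && grepl("mean|mass|age|height|weight|waist|sbp|dbp|glucose|chol|hdl|homa|triglycerides|kcal|snack_delta|score|pa_min", nm) && v[2] < 0) {
        stop_field(field, "SD must be >= 0")
      }
      if (grepl("_sd$", nm) && v[1] < 0) stop_field(field, "SD must be >= 0")
      if (grepl("_prob$", nm) && (v[1] < 0 || v[1] > 1)) {
        stop_field(field, "probability must be in [0, 1]")
      }
    }
  }
  invisible(config)
}

rnorm2 <- function(n, ms) rnorm(n, ms[1], ms[2])
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort with planted effects
#'
#' Simulates participants, three recall days each (two working, one
#' non-working), seven sleep nights each (five working, two weekend), and a
#' biomarker panel. Meal and sleep timing arise from participant-level
#' latent variables (weekly midsleep point, sleep duration, eating window,
#' midsleep-to-first-intake interval, social and eating jetlag) plus
#' night-to-night and day-to-day Gaussian jitter, so the pipeline's weekly
#' summaries recover the configured marginals at large n.
#'
#' log10 HOMA-IR in men is generated from the *derived* weekly eating window
#' and midsleep-to-first-intake interval (computed from the generated tables
#' by the package's own metric functions, standardized within stratum), with
#' coefficients solved from the two planted simple-regression standardized
#' slopes so that refitting either simple regression recovers its planted
#' value in expectation despite the exposures' slight correlation. Women's
#' slopes are zero. Insulin is derived as `HOMA x 405 / glucose`, keeping
#' the HOMA-IR identity exact in the synthetic data.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `participants`, `recall_events`,
#'   `sleep_nights`, `truth` (the planted slopes), and `derived` (the weekly
#'   profile used when planting the effects).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- as.integer(config$n_participants)
  mg <- config$marginals
  n_women <- as.integer(round(n * config$fraction_women))
  sex <- rep(c("woman", "man"), c(n_women, n - n_women))
  pid <- sprintf("P%05d", seq_len(n))

  # participant-level latents
  sl <- mg$sleep; ml <- mg$meals
  ms_week <- rnorm(n, sl$midsleep_mean, sl$midsleep_sd)          # noon axis
  sj <- rnorm(n, sl$social_jetlag_mean, sl$social_jetlag_sd)
  dur <- clip(rnorm(n, sl$duration_mean, sl$duration_sd), 4, 12)
  # expected weekly shrinkage caused by deleting a skipped breakfast:
  # the day's first intake jumps to the morning snack (delta later), and a
  # random recall day carries expected weekly weight 1/3
  skip_comp <- config$breakfast_skip_prob * ml$morning_snack_delta[1] / 3
  win <- clip(rnorm(n, ml$eating_window_mean + skip_comp,
                    ml$eating_window_sd), 6, 18)
  m2f <- clip(rnorm(n, ml$msp_to_first_mean - skip_comp,
                    ml$msp_to_first_sd), 1, 12)
  ejl <- rnorm(n, ml$eating_jetlag_mean, ml$eating_jetlag_sd)

  ms_working <- ms_week - (2 / 7) * sj
  ms_nonworking <- ms_working + sj
  first_week <- from_noon_axis(ms_week) + m2f       # within-day axis, clock
  first_working <- first_week - (2 / 7) * ejl
  first_nonworking <- first_working + ejl

  sleep_nights <- make_sleep_nights(pid, ms_working, ms_nonworking, dur, sl)
  recall_events <- make_recall_events(pid, first_working, first_nonworking,
                                      win, ml)
  recall_events <- apply_breakfast_skipping(recall_events, pid,
                                            config$breakfast_skip_prob)

  sleep_summary <- weekly_sleep_summary(sleep_nights)
  profile <- weekly_chrono_profile(recall_events, sleep_summary)
  profile <- profile[match(pid, profile$participant_id), ]

  participants <- make_participants(pid, sex, mg, profile, config)

  truth <- tibble(
    stratum = rep(c("man", "woman"), each = 2),
    exposure = rep(c("eating_window", "msp_to_first"), 2),
    outcome = "log10_homa_ir",
    beta_std = c(config$effect_beta_window_homa_men,
                 config$effect_beta_msp2first_homa_men, 0, 0)
  )

  structure(list(participants = participants,
                 recall_events = recall_events,
                 sleep_nights = sleep_nights,
                 truth = truth,
                 derived = profile),
            class = "synthetic_cohort")
}

make_sleep_nights <- function(pid, ms_working, ms_nonworking, dur, sl) {
  n <- length(pid)
  # onset dates Mon..Sun; wake days Fri/Sat nights are non-working
  night_dates <- as.Date("2015-10-05") + 0:6
  working_night <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  idx <- rep(seq_len(n), each = 7)
  nd <- rep(1:7, n)
  stratum_ms <- ifelse(working_night[nd], ms_working[idx], ms_nonworking[idx])
  ms_night <- stratum_ms + rnorm(7 * n, 0, sl$night_jitter_sd)
  dur_night <- clip(dur[idx] + rnorm(7 * n, 0, sl$night_jitter_sd), 3, 14)
  onset <- ms_night - dur_night / 2
  offset <- ms_night + dur_night / 2
  tibble(
    participant_id = pid[idx],
    date = night_dates[nd],
    day_type = ifelse(working_night[nd], "working", "non-working"),
    onset = onset,
    offset = offset,
    wear_hours = clip(rnorm(7 * n, sl$wear_mean, sl$wear_sd), 0, 24),
    duration = dur_night
  )
}

make_recall_events <- function(pid, first_working, first_nonworking, win, ml) {
  n <- length(pid)
  recall_dates <- as.Date(c("2015-10-13", "2015-10-21", "2015-10-25"))
  recall_types <- c("working", "working", "non-working")
  rows <- list()
  for (d in 1:3) {
    first_anchor <- if (recall_types[d] == "working") first_working else first_nonworking
    # events must stay inside one within-day span (04:00 .. 28:00) so the
    # CSV round-trip through clock times is lossless
    first_d <- clip(first_anchor + rnorm(n, 0, ml$meal_jitter_sd), 4.5, 20)
    last_d <- clip(first_d + clip(win + rnorm(n, 0, ml$meal_jitter_sd), 4, 20),
                   first_d + 4, 27.5)
    msnack_d <- first_d + clip(rnorm2(n, ml$morning_snack_delta), 0.5, 4)
    lunch_d <- (first_d + last_d) / 2 + rnorm(n, 0, ml$meal_jitter_sd)
    lunch_d <- clip(lunch_d, msnack_d + 0.5, last_d - 1)
    esnack_d <- runif(n, lunch_d + 0.5, last_d - 0.5)
    has_esnack <- runif(n) < ml$evening_snack_prob
    day <- tibble(
      participant_id = rep(pid, 5),
      date = recall_dates[d],
      day_type = recall_types[d],
      day_hour = c(first_d, msnack_d, lunch_d, esnack_d, last_d),
      energy = pmax(c(rnorm2(n, ml$kcal_breakfast), rnorm2(n, ml$kcal_snack),
                      rnorm2(n, ml$kcal_lunch), rnorm2(n, ml$kcal_snack),
                      rnorm2(n, ml$kcal_dinner)), 10),
      meal_label = rep(c("breakfast", "snack", "lunch", "snack", "dinner"),
                       each = n),
      keep = c(rep(TRUE, 3 * n), has_esnack, rep(TRUE, n))
    )
    rows[[d]] <- day[day$keep, names(day) != "keep"]
  }
  events <- bind_rows(rows)
  events$clock_time <- events$day_hour %% 24
  events$is_caloric <- events$energy > 0
  events$entry_id <- NA_character_
  arrange(events, .data$participant_id, .data$date, .data$day_hour)
}

apply_breakfast_skipping <- function(events, pid, skip_prob) {
  skips <- runif(length(pid)) < skip_prob
  skip_day <- sample(1:3, length(pid), replace = TRUE)
  dates <- sort(unique(events$date))
  drop_key <- paste(pid[skips], dates[skip_day[skips]])
  events |>
    group_by(.data$participant_id, .data$date) |>
    mutate(.drop_first = paste(.data$participant_id[1], .data$date[1]) %in%
             drop_key & row_number() == 1) |>
    ungroup() |>
    filter(!.data$.drop_first) |>
    select(-".drop_first")
}

make_participants <- function(pid, sex, mg, profile, config) {
  n <- length(pid)
  par <- function(nm) {
    m <- ifelse(sex == "man", mg$man[[nm]][1], mg$woman[[nm]][1])
    s <- ifelse(sex == "man", mg$man[[nm]][2], mg$woman[[nm]][2])
    rnorm(n, m, s)
  }
  age <- clip(par("age"), 18, 25)
  height <- clip(par("height"), 140, 210)
  weight <- clip(par("weight"), 40, 160)
  lean_mass <- clip(par("lean_mass"), 20, 90)
  waist <- clip(par("waist"), 50, 160)
  dbp <- clip(par("dbp"), 45, 110)
  sbp <- pmax(clip(par("sbp"), 80, 180), dbp + 5)
  glucose <- clip(par("glucose"), 60, 140)
  log10_tg <- par("log10_triglycerides")
  total_chol <- clip(par("total_chol"), 80, 320)
  hdl <- clip(par("hdl"), 20, 110)

  log10_homa <- plant_homa(sex, profile, mg, config)
  homa <- 10^log10_homa
  insulin <- homa * 405 / glucose

  visit_sd <- mg$covariates$bp_visit_sd
  sbp_visits <- replicate(3, sbp + rnorm(n, 0, visit_sd))
  dbp_visits <- replicate(3, dbp + rnorm(n, 0, visit_sd))
  sbp_visits <- pmax(sbp_visits, dbp_visits + 1)

  tibble(
    participant_id = pid,
    sex = sex,
    age = round(age, 1),
    height_cm = height,
    weight_kg = weight,
    lean_mass_kg = lean_mass,
    waist_cm = waist,
    sbp_1 = sbp_visits[, 1], sbp_2 = sbp_visits[, 2], sbp_3 = sbp_visits[, 3],
    dbp_1 = dbp_visits[, 1], dbp_2 = dbp_visits[, 2], dbp_3 = dbp_visits[, 3],
    glucose = glucose,
    insulin = insulin,
    triglycerides = 10^log10_tg,
    total_chol = total_chol,
    hdl = hdl,
    med_diet_score = clip(rnorm2(n, mg$covariates$med_diet_score), 0, 14),
    light_pa_min = clip(rnorm2(n, mg$covariates$light_pa_min), 0, 600)
  )
}

# Solve for the generating coefficients a = R^-1 tau so that the simple
# regressions of log10 HOMA on each standardized derived exposure have the
# planted standardized slopes tau in expectation.
plant_homa <- function(sex, profile, mg, config) {
  n <- length(sex)
  log10_homa <- numeric(n)
  for (s in c("man", "woman")) {
    idx <- which(sex == s)
    pars <- mg[[s]]$log10_homa
    if (s == "woman") {
      log10_homa[idx] <- rnorm(length(idx), pars[1], pars[2])
      next
    }
    z1 <- as.numeric(scale(profile$eating_window[idx]))
    z2 <- as.numeric(scale(profile$msp_to_first[idx]))
    if (anyNA(z1) || anyNA(z2)) {
      abort("derived exposures are incomplete in the men stratum")
    }
    r12 <- stats::cor(z1, z2)
    tau <- c(config$effect_beta_window_homa_men,
             config$effect_beta_msp2first_homa_men)
    if (length(idx) >= 10 && abs(r12) < 0.9) {
      a <- solve(matrix(c(1, r12, r12, 1), 2), tau)
      q <- sum(a^2) + 2 * a[1] * a[2] * r12
      if (q > 0.99) {
        stop_field("effect_beta_window_homa_men",
                   "planted effects imply a near-deterministic outcome")
      }
      # residual noise orthogonalized against the exposures and
      # standardized, so the in-sample simple-regression slopes equal the
      # planted values exactly rather than up to O(1/sqrt(n)) noise
      eps <- stats::residuals(lm(rnorm(length(idx)) ~ z1 + z2))
      eps <- eps / sd(eps)
    } else {
      # strata too small (or too collinear) for the exact solve: plant the
      # slopes directly with independent noise
      a <- tau
      q <- min(sum(a^2) + 2 * a[1] * a[2] * r12, 0.99)
      eps <- rnorm(length(idx))
    }
    y <- a[1] * z1 + a[2] * z2 + sqrt(1 - q) * eps
    log10_homa[idx] <- pars[1] + pars[2] * y
  }
  log10_homa
}

#' Emit dual (and conditional third) dietician entries
#'
#' Produces the fixture for the reconciliation rule: each recall day of the
#' cohort appears under entry IDs `A` and `B`, with daily energy totals
#' differing by a coefficient of variation drawn half-normal with SD
#' `dual_entry_cv_sd` percent. Days whose realized CV exceeds the 5%
#' threshold additionally receive a third entry `C` (a re-entry with small,
#' ~1% CV deviation from `A`). Event times are identical across entries;
#' entry `B`/`C` scale every event energy by the factor implied by the drawn
#' CV.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The [cohort_config()] used (supplies `dual_entry_cv_sd` and
#'   the seed; a derived seed keeps the draw independent of the cohort's).
#' @param cv_threshold Threshold (percent) above which a third entry is
#'   emitted.
#' @return A meal-event tibble with an `entry_id` column.
#' @export
emit_dual_entries <- function(cohort, config, cv_threshold = 5) {
  events <- cohort$recall_events
  withr::with_seed((config$seed + 77777) %% .Machine$integer.max, {
    key <- paste(events$participant_id, events$date)
    days <- unique(key)
    cv <- abs(rnorm(length(days), 0, config$dual_entry_cv_sd))
    k <- cv_to_ratio(cv)
    flip <- runif(length(days)) < 0.5
    k <- ifelse(flip, 1 / k, k)
    names(k) <- days
    a <- events; a$entry_id <- "A"
    b <- events; b$entry_id <- "B"
    b$energy <- b$energy * k[key]
    out <- bind_rows(a, b)
    third_days <- days[cv > cv_threshold]
    if (length(third_days) > 0) {
      cv3 <- abs(rnorm(length(third_days), 0, 1))
      k3 <- cv_to_ratio(cv3)
      names(k3) <- third_days
      c_ev <- events[key %in% third_days, , drop = FALSE]
      c_ev$entry_id <- "C"
      c_ev$energy <- c_ev$energy *
        k3[paste(c_ev$participant_id, c_ev$date)]
      out <- bind_rows(out, c_ev)
    }
    arrange(out, .data$participant_id, .data$date, .data$entry_id,
            .data$day_hour)
  })
}

# Energy-scaling factor k such that CV(total, k * total) equals cv percent:
# CV = 100 * sqrt(2) * (k - 1) / (k + 1).
cv_to_ratio <- function(cv) {
  s <- 100 * sqrt(2)
  (s + cv) / (s - cv)
}

#' Write the cohort input CSVs
#'
#' Serializes the three input tables consumed by the pipeline readers, with
#' ISO dates and `"HH:MM"` clock times: `recalls.csv`, `sleep.csv`,
#' `participants.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param dual_entries Optional event table from [emit_dual_entries()] to
#'   write instead of the clean recall events.
#' @return Invisibly, the paths written.
#' @export
write_cohort_csvs <- function(cohort, dir, dual_entries = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- dual_entries %||% cohort$recall_events
  recalls <- tibble(
    participant_id = ev$participant_id,
    date = ev$date,
    day_type = ev$day_type,
    time = format_clock_time(ev$clock_time),
    energy_kcal = round(ev$energy, 1),
    meal_label = ev$meal_label,
    entry_id = ev$entry_id
  )
  sn <- cohort$sleep_nights
  sleep <- tibble(
    participant_id = sn$participant_id,
    date = sn$date,
    day_type = sn$day_type,
    onset = format_clock_time(sn$onset),
    offset = format_clock_time(sn$offset),
    wear_hours = round(sn$wear_hours, 2)
  )
  paths <- c(recalls = file.path(dir, "recalls.csv"),
             sleep = file.path(dir, "sleep.csv"),
             participants = file.path(dir, "participants.csv"))
  readr::write_csv(recalls, paths["recalls"], progress = FALSE)
  readr::write_csv(sleep, paths["sleep"], progress = FALSE)
  readr::write_csv(cohort$participants |>
                     mutate(across(-c("participant_id", "sex"),
                                   ~ round(.x, 4))),
                   paths["participants"], progress = FALSE)
  invisible(paths)
}
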