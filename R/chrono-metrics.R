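caloric_events <- function(day) {
  day[day$is_caloric, , drop = FALSE]
}

#' Daily eating window
#'
#' Elapsed time (hours) between the first and the last caloric intake of a
#' recall day, on the within-day axis (a 00:30 snack belonging to the
#' evening counts as 24.5 h).
#'
#' @param day A recall day from [as_recall_day()].
#' @return Hours, or `NA` when the day has no caloric event.
#' @export
daily_eating_window <- function(day) {
  ev <- caloric_events(day)
  if (nrow(ev) == 0) return(NA_real_)
  max(ev$day_hour) - min(ev$day_hour)
}

#' Daily caloric midpoint
#'
#' Local time at which the running cumulative energy intake first reaches at
#' least 50% of the day's total, with each event's energy counted at its
#' clock time.
#'
#' @inheritParams daily_eating_window
#' @param clock If `TRUE` (default) report on the clock in `[0, 24)`,
#'   otherwise on the within-day axis.
#' @return Decimal hours, or `NA` when the day has zero caloric energy.
#' @export
daily_caloric_midpoint <- function(day, clock = TRUE) {
  ev <- caloric_events(day)
  total <- sum(ev$energy)
  if (nrow(ev) == 0 || total <= 0) return(NA_real_)
  cum <- cumsum(ev$energy)
  t <- ev$day_hour[which(cum >= total / 2)[1]]
  if (clock) t %% 24 else t
}

#' Daily eating midpoint
#'
#' Temporal midpoint of the eating window: `(first + last caloric intake
#' time) / 2` on the within-day axis. This is the construct entering eating
#' jetlag, and is distinct from the (energy-weighted) caloric midpoint.
#'
#' @inheritParams daily_caloric_midpoint
#' @return Decimal hours, or `NA` when the day has no caloric event.
#' @export
daily_eating_midpoint <- function(day, clock = TRUE) {
  ev <- caloric_events(day)
  if (nrow(ev) == 0) return(NA_real_)
  t <- (min(ev$day_hour) + max(ev$day_hour)) / 2
  if (clock) t %% 24 else t
}

#' Eating jetlag
#'
#' Variability of the eating midpoint between non-working and working days:
#' `eating midpoint (non-working) - eating midpoint (working)`, in hours and
#' signed (positive = later eating on free days). Inputs must be on a
#' linearized (within-day) axis.
#'
#' @param midpoint_nonworking,midpoint_working Stratum mean eating midpoints
#'   (within-day axis, decimal hours).
#' @return Signed hours, `NA` if a stratum is missing.
#' @export
eating_jetlag <- function(midpoint_nonworking, midpoint_working) {
  ifelse(is.na(midpoint_nonworking) | is.na(midpoint_working),
         NA_real_, midpoint_nonworking - midpoint_working)
}

#' Interval from the midsleep point to the first food intake
#'
#' `(first intake - midsleep) mod 24`, in `(0, 24)`. Values close to 24
#' indicate a first intake recorded *before* the midsleep point and are left
#' as-is for quality control rather than silently re-ordered.
#'
#' @param first_intake Weekly mean clock time of the first caloric intake
#'   (decimal hours).
#' @param midsleep Weekly midsleep point (clock, decimal hours).
#' @return Hours in `[0, 24)`; `NA` propagates.
#' @export
msp_to_first_intake <- function(first_intake, midsleep) {
  ifelse(is.na(first_intake) | is.na(midsleep),
         NA_real_, circ_diff(midsleep, first_intake))
}

#' Interval from the last food intake to the midsleep point
#'
#' `(midsleep - last intake) mod 24`; the mirror of
#' [msp_to_first_intake()].
#'
#' @param last_intake Weekly mean clock time of the last caloric intake.
#' @param midsleep Weekly midsleep point (clock, decimal hours).
#' @return Hours in `[0, 24)`; `NA` propagates.
#' @export
last_intake_to_msp <- function(last_intake, midsleep) {
  ifelse(is.na(last_intake) | is.na(midsleep),
         NA_real_, circ_diff(last_intake, midsleep))
}

#' Breakfast consumer / skipper classification
#'
#' A participant is a breakfast *consumer* when every one of the three
#' recall days shows a qualifying breakfast, and a *skipper* when at least
#' one day lacks one. A qualifying breakfast is a caloric event of at least
#' `min_kcal` no later than `cutoff`; an event labelled `"breakfast"` in
#' `meal_label` qualifies regardless of the time rule.
#'
#' @param days List of exactly three recall days for one participant.
#' @param cutoff Latest clock time (decimal hours) counted as breakfast.
#' @param min_kcal Minimum energy of a qualifying breakfast event.
#' @return `"consumer"` or `"skipper"`.
#' @export
classify_breakfast <- function(days, cutoff = 11, min_kcal = 50) {
  if (length(days) != 3) {
    abort(sprintf("breakfast classification requires exactly 3 recall days, got %d",
                  length(days)), class = "chronomeal_classification_error")
  }
  has_breakfast <- vapply(days, function(day) {
    labelled <- !is.na(day$meal_label) &
      tolower(day$meal_label) == "breakfast" & day$is_caloric
    timed <- day$is_caloric & day$energy >= min_kcal & day$clock_time <= cutoff
    any(labelled) || any(timed)
  }, logical(1))
  if (all(has_breakfast)) "consumer" else "skipper"
}

# Vectorized per-day metrics on a long event table (caloric events only).
# Reproduces daily_eating_window() / daily_caloric_midpoint() /
# daily_eating_midpoint() for every participant-date at once; the two paths
# are asserted equivalent in the test suite.
per_day_metrics <- function(events, breakfast_cutoff = 11,
                            breakfast_min_kcal = 50) {
  events |>
    filter(.data$is_caloric) |>
    arrange(.data$participant_id, .data$date, .data$day_hour) |>
    group_by(.data$participant_id, .data$date, .data$day_type) |>
    summarise(
      window = max(.data$day_hour) - min(.data$day_hour),
      first_intake = min(.data$day_hour),
      last_intake = max(.data$day_hour),
      eating_mid = (min(.data$day_hour) + max(.data$day_hour)) / 2,
      caloric_mid = .data$day_hour[
        which(cumsum(.data$energy) >= sum(.data$energy) / 2)[1]],
      has_breakfast = any((!is.na(.data$meal_label) &
                             tolower(.data$meal_label) == "breakfast") |
                            (.data$energy >= breakfast_min_kcal &
                               .data$clock_time <= breakfast_cutoff)),
      .groups = "drop"
    )
}

# Weighted weekly mean of a per-day column; working stratum is the mean of
# the working recall days, non-working likewise.
weekly_from_daily <- function(per_day, weights = c(5, 2)) {
  per_day |>
    pivot_longer(c("window", "first_intake", "last_intake", "eating_mid",
                   "caloric_mid"),
                 names_to = "metric") |>
    group_by(.data$participant_id, .data$metric) |>
    summarise(
      w = mean(.data$value[.data$day_type == "working"]),
      n = mean(.data$value[.data$day_type == "non-working"]),
      .groups = "drop"
    ) |>
    mutate(week = ifelse(is.nan(.data$w) | is.nan(.data$n), NA_real_,
                         (weights[1] * .data$w + weights[2] * .data$n) /
                           sum(weights)))
}

#' Weekly chrononutrition profile per participant
#'
#' Computes per-day metrics for the three recall days (2 working, 1
#' non-working), averages them within day-type strata, combines strata with
#' the same 5/7-2/7 week weighting used for sleep, and anchors the weekly
#' first/last intake times on the weekly midsleep point. Because recall days
#' and actigraphy days do not overlap by design, the midsleep-anchored
#' intervals are differences of *weekly means*, not day-matched pairs.
#'
#' @param recall_days List of recall days ([build_recall_days()]) or a
#'   single long event tibble covering all participants.
#' @param sleep_summary Output of [weekly_sleep_summary()].
#' @param weights Week weights `c(working, nonworking)`.
#' @param breakfast_cutoff,breakfast_min_kcal Passed to
#'   [classify_breakfast()].
#' @return One row per participant with eating window, caloric midpoint,
#'   eating midpoint strata, signed and absolute eating jetlag, the two
#'   midsleep-anchored intervals and breakfast status. Participants invalid
#'   under the actigraphy filter keep their recall-only metrics but get `NA`
#'   midsleep-anchored columns.
#' @export
weekly_chrono_profile <- function(recall_days, sleep_summary,
                                  weights = c(5, 2),
                                  breakfast_cutoff = 11,
                                  breakfast_min_kcal = 50) {
  events <- if (is.data.frame(recall_days)) {
    as_tibble(recall_days)
  } else {
    bind_rows(map(recall_days, as_tibble))
  }
  events$participant_id <- as.character(events$participant_id)
  per_day <- per_day_metrics(events, breakfast_cutoff, breakfast_min_kcal)
  weekly <- weekly_from_daily(per_day, weights) |>
    select("participant_id", "metric", "w", "n", "week") |>
    pivot_wider(names_from = "metric",
                values_from = c("w", "n", "week"))
  breakfast <- per_day |>
    group_by(.data$participant_id) |>
    summarise(
      n_recall_days = n(),
      breakfast_status = ifelse(n() == 3,
                                ifelse(all(.data$has_breakfast),
                                       "consumer", "skipper"),
                                NA_character_),
      .groups = "drop"
    )
  msp <- sleep_summary |>
    filter(.data$valid) |>
    select("participant_id", "midsleep_week")
  weekly |>
    left_join(breakfast, by = "participant_id") |>
    left_join(msp, by = "participant_id") |>
    mutate(
      eating_window = .data$week_window,
      caloric_midpoint = .data$week_caloric_mid %% 24,
      eating_midpoint_working = .data$w_eating_mid %% 24,
      eating_midpoint_nonworking = .data$n_eating_mid %% 24,
      eating_jetlag = eating_jetlag(.data$n_eating_mid, .data$w_eating_mid),
      eating_jetlag_abs = abs(.data$eating_jetlag),
      first_intake_week = .data$week_first_intake %% 24,
      last_intake_week = .data$week_last_intake %% 24,
      msp_to_first = msp_to_first_intake(.data$first_intake_week,
                                         .data$midsleep_week),
      last_to_msp = last_intake_to_msp(.data$last_intake_week,
                                       .data$midsleep_week)
    ) |>
    select("participant_id", "n_recall_days", "eating_window",
           "caloric_midpoint", "eating_midpoint_working",
           "eating_midpoint_nonworking", "eating_jetlag", "eating_jetlag_abs",
           "first_intake_week", "last_intake_week", "msp_to_first",
           "last_to_msp", "breakfast_status")
}
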