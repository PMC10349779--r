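#' Read a sleep night table
#'
#' One row per night: `participant_id`, `date` (day of sleep onset, ISO),
#' `day_type` of the following wake day (`"working"`/`"non-working"`),
#' `onset` and `offset` clock times (`"HH:MM"` or decimal hours), and
#' `wear_hours` of accelerometer wear for the day. Onset and offset are
#' re-expressed on the noon-anchored axis `[12, 36)`; an offset earlier than
#' onset on that axis is taken to fall on the next day.
#'
#' @param path Path to the CSV file.
#' @return A tibble of sleep nights with `onset`/`offset` on the
#'   noon-anchored axis and a `duration` column in hours.
#' @export
read_sleep_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("sleep file not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant_id", "date", "day_type", "onset", "offset",
                "wear_hours")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("sleep table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "chronomeal_schema_error")
  }
  onset <- to_noon_axis(parse_clock_time(raw$onset))
  offset <- to_noon_axis(parse_clock_time(raw$offset))
  offset <- ifelse(offset <= onset, offset + 24, offset)
  if (any(!is.na(raw$wear_hours) & (raw$wear_hours < 0 | raw$wear_hours > 24))) {
    abort_rows("wear_hours outside [0, 24]",
               which(raw$wear_hours < 0 | raw$wear_hours > 24))
  }
  nights <- tibble(
    participant_id = as.character(raw$participant_id),
    date = as.Date(raw$date),
    day_type = check_day_type(raw$day_type),
    onset = onset,
    offset = offset,
    wear_hours = as.numeric(raw$wear_hours)
  )
  nights$duration <- nights$offset - nights$onset
  bad <- nights$duration <= 0 | nights$duration >= 24
  if (any(bad, na.rm = TRUE)) {
    abort_rows("sleep duration must be in (0, 24) h", which(bad))
  }
  nights
}

#' Actigraphy validity filter
#'
#' A participant's week of recordings is invalid when wear time was below
#' `min_wear_hours` (16 h) on more than `max_low_wear_days` (4) days, or
#' when no non-working (weekend) day was recorded. Invalid participants are
#' excluded from all sleep-referenced analyses.
#'
#' @param nights Sleep-night tibble for one participant (at most 7 rows).
#' @param min_wear_hours Daily wear-time threshold in hours.
#' @param max_low_wear_days Maximum tolerated number of low-wear days.
#' @return `TRUE` if the recording week is usable, `FALSE` otherwise (with a
#'   `reason` attribute naming the failed rule).
#' @export
is_valid_actigraphy <- function(nights, min_wear_hours = 16,
                                max_low_wear_days = 4) {
  if (is.null(nights) || nrow(nights) == 0) {
    return(structure(FALSE, reason = "no sleep nights recorded"))
  }
  if (nrow(nights) > 7) {
    abort("at most 7 nights per participant expected")
  }
  low_wear <- sum(nights$wear_hours < min_wear_hours, na.rm = TRUE)
  if (low_wear > max_low_wear_days) {
    return(structure(FALSE, reason = sprintf(
      "wear time < %g h on %d days (> %d allowed)",
      min_wear_hours, low_wear, max_low_wear_days)))
  }
  if (!any(nights$day_type == "non-working")) {
    return(structure(FALSE, reason = "no non-working (weekend) day recorded"))
  }
  TRUE
}

#' Midsleep point of a single night
#'
#' Midsleep point (local time) = sleep onset + sleep duration / 2, reported
#' on the clock in `[0, 24)`. The computation is done on the noon-anchored
#' axis so nights that wrap midnight average correctly.
#'
#' @param onset,offset Sleep onset/offset, decimal hours (clock or
#'   noon-anchored axis; offset may exceed 24).
#' @return Midsleep clock time in decimal hours.
#' @examples
#' nightly_midsleep(23, 31) # 03:00
#' @export
nightly_midsleep <- function(onset, offset) {
  onset_na <- to_noon_axis(onset)
  offset_na <- to_noon_axis(offset)
  offset_na <- ifelse(offset_na <= onset_na, offset_na + 24, offset_na)
  from_noon_axis(onset_na + (offset_na - onset_na) / 2)
}

#' Weighted weekly mean of working / non-working stratum values
#'
#' The week is summarized as `(5 * working + 2 * nonworking) / 7`. Clock
#' times must be supplied on the noon-anchored (or any linearized) axis;
#' the weights are configurable but default to the 5/2 working/weekend split
#' of a standard week.
#'
#' @param working_value,nonworking_value Stratum means (same units).
#' @param weights Length-2 numeric `c(working, nonworking)` weights.
#' @return The weighted mean, same units as the inputs.
#' @export
weighted_week_mean <- function(working_value, nonworking_value,
                               weights = c(5, 2)) {
  if (any(is.na(working_value)) || any(is.na(nonworking_value))) {
    abort("both stratum values are required for the weekly weighted mean",
          class = "chronomeal_missing_stratum_error")
  }
  (weights[1] * working_value + weights[2] * nonworking_value) / sum(weights)
}

#' Social jetlag
#'
#' Midsleep point on non-working days minus midsleep point on working days,
#' in hours (signed; positive when sleep is later on free days). Inputs must
#' be on the noon-anchored axis.
#'
#' @param midsleep_nonworking,midsleep_working Stratum midsleep points on
#'   the noon-anchored axis.
#' @return Signed social jetlag in hours.
#' @export
social_jetlag <- function(midsleep_nonworking, midsleep_working) {
  if (any(is.na(midsleep_nonworking)) || any(is.na(midsleep_working))) {
    abort("both stratum midsleep points are required",
          class = "chronomeal_missing_stratum_error")
  }
  midsleep_nonworking - midsleep_working
}

#' Weekly sleep summary per participant
#'
#' Applies the validity filter, computes per-night midsleep points on the
#' noon-anchored axis, averages within day-type strata, and combines strata
#' with [weighted_week_mean()]. Social jetlag is reported signed with an
#' accompanying magnitude column.
#'
#' @param nights Sleep-night tibble (all participants).
#' @param weights Week weights passed to [weighted_week_mean()].
#' @param min_wear_hours,max_low_wear_days Passed to [is_valid_actigraphy()].
#' @return One row per participant: weekly/stratum midsleep (clock, decimal
#'   hours), weekly sleep duration, social jetlag, and a `valid` flag with
#'   `exclusion_reason` for filtered participants. Noon-axis midsleep values
#'   are kept in `midsleep_week_na` for downstream interval arithmetic.
#' @export
weekly_sleep_summary <- function(nights, weights = c(5, 2),
                                 min_wear_hours = 16, max_low_wear_days = 4) {
  nights <- as_tibble(nights)
  nights$participant_id <- as.character(nights$participant_id)
  if (!"duration" %in% names(nights)) {
    on_na <- to_noon_axis(nights$onset)
    off_na <- to_noon_axis(nights$offset)
    nights$duration <- ifelse(off_na <= on_na, off_na + 24, off_na) - on_na
  }
  nights$ms_na <- to_noon_axis(nightly_midsleep(nights$onset, nights$offset))
  out <- nights |>
    group_by(.data$participant_id) |>
    summarise(
      n_nights = n(),
      low_wear = sum(.data$wear_hours < min_wear_hours, na.rm = TRUE),
      has_weekend = any(.data$day_type == "non-working"),
      msw = mean(.data$ms_na[.data$day_type == "working"]),
      msn = mean(.data$ms_na[.data$day_type == "non-working"]),
      dw = mean(.data$duration[.data$day_type == "working"]),
      dn = mean(.data$duration[.data$day_type == "non-working"]),
      .groups = "drop"
    ) |>
    mutate(
      valid = .data$low_wear <= max_low_wear_days & .data$has_weekend,
      exclusion_reason = case_when(
        .data$low_wear > max_low_wear_days ~ sprintf(
          "wear time < %g h on more than %d days", min_wear_hours,
          max_low_wear_days),
        !.data$has_weekend ~ "no non-working (weekend) day recorded",
        TRUE ~ NA_character_
      )
    )
  week_na <- ifelse(out$valid,
                    (weights[1] * out$msw + weights[2] * out$msn) /
                      sum(weights), NA_real_)
  tibble(
    participant_id = out$participant_id,
    valid = out$valid,
    exclusion_reason = out$exclusion_reason,
    midsleep_week = from_noon_axis(week_na),
    midsleep_week_na = week_na,
    midsleep_working = ifelse(out$valid, from_noon_axis(out$msw), NA_real_),
    midsleep_nonworking = ifelse(out$valid, from_noon_axis(out$msn), NA_real_),
    sleep_duration_week = ifelse(
      out$valid,
      (weights[1] * out$dw + weights[2] * out$dn) / sum(weights), NA_real_),
    social_jetlag = ifelse(out$valid, out$msn - out$msw, NA_real_),
    social_jetlag_abs = ifelse(out$valid, abs(out$msn - out$msw), NA_real_)
  )
}
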