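#' Read a dietary recall event table
#'
#' Reads a CSV of timed eating events, one row per event. Required columns:
#' `participant_id`, `date` (ISO), `day_type` (`"working"`/`"non-working"`),
#' `time` (`"HH:MM"` or decimal hours), `energy_kcal`. Optional:
#' `meal_label`, `entry_id` (`"A"`/`"B"`/`"C"`, present when a recall day was
#' entered independently by two dieticians and possibly a third).
#'
#' Events with energy at or below `caloric_threshold` are retained but
#' flagged `is_caloric = FALSE`; they never contribute to eating-window or
#' caloric-midpoint calculations.
#'
#' @param path Path to the CSV file.
#' @param caloric_threshold Energy (kcal) at or below which an event is
#'   considered non-caloric. Default 0 (any positive energy is caloric).
#' @param day_start Within-day axis boundary passed to [within_day_axis()].
#' @return A tibble of meal events with `clock_time` (decimal hours in
#'   `[0, 24)`), `day_hour` (within-day axis) and `is_caloric` columns.
#' @export
read_recall_table <- function(path, caloric_threshold = 0, day_start = 4) {
  if (!file.exists(path)) {
    abort(sprintf("recall file not found: %s", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant_id", "date", "day_type", "time", "energy_kcal")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("recall table is missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "chronomeal_schema_error")
  }
  if (any(!is.na(raw$energy_kcal) & raw$energy_kcal < 0)) {
    abort_rows("negative energy_kcal", which(raw$energy_kcal < 0))
  }
  events <- tibble(
    participant_id = as.character(raw$participant_id),
    date = as.Date(raw$date),
    day_type = check_day_type(raw$day_type),
    clock_time = parse_clock_time(raw$time),
    energy = as.numeric(raw$energy_kcal),
    meal_label = if ("meal_label" %in% names(raw)) as.character(raw$meal_label) else NA_character_,
    entry_id = if ("entry_id" %in% names(raw)) as.character(raw$entry_id) else NA_character_
  )
  events$day_hour <- within_day_axis(events$clock_time, day_start)
  events$is_caloric <- !is.na(events$energy) & events$energy > caloric_threshold
  events
}

check_day_type <- function(x) {
  x <- as.character(x)
  ok <- is.na(x) | x %in% c("working", "non-working")
  if (!all(ok)) {
    abort_rows(sprintf("day_type must be \"working\" or \"non-working\", got %s",
                       encodeString(x[which(!ok)[1]], quote = '"')),
               which(!ok))
  }
  x
}

#' Coefficient of variation between two daily energy totals
#'
#' The agreement statistic of the dual-entry rule: two dieticians enter the
#' same 24-h recall independently and their daily energy totals are compared
#' by the coefficient of variation, `100 * sd / mean` with the sample
#' (n - 1) SD convention. Totals differing by more than 5% trigger a third
#' entry.
#'
#' @param total_a,total_b Daily energy totals (kcal) of the two entries.
#' @return CV in percent.
#' @examples
#' energy_cv(2000, 2000) # 0
#' energy_cv(100, 110)   # 6.734
#' @export
energy_cv <- function(total_a, total_b) {
  if (!is.finite(total_a) || !is.finite(total_b) || total_a < 0 || total_b < 0) {
    abort("energy totals must be finite and non-negative")
  }
  m <- mean(c(total_a, total_b))
  if (m == 0) {
    abort("coefficient of variation undefined: both totals are zero",
          class = "chronomeal_cv_error")
  }
  100 * sd(c(total_a, total_b)) / m
}

#' Assemble one recall day
#'
#' Orders events on the within-day axis and computes the daily energy total
#' (caloric events only). A `recall_day` is an ordered event tibble for a
#' single participant-date; downstream per-day metrics operate on it.
#'
#' @param events Event tibble for one participant-date (as produced by
#'   [read_recall_table()]).
#' @return The event tibble sorted by `day_hour`, with attributes
#'   `total_energy`, `participant_id`, `date`, `day_type`.
#' @export
as_recall_day <- function(events) {
  stopifnot(is.data.frame(events))
  if (length(unique(events$participant_id)) > 1 || length(unique(events$date)) > 1) {
    abort("a recall day must contain a single participant-date")
  }
  events <- events[order(events$day_hour), , drop = FALSE]
  structure(as_tibble(events),
            total_energy = sum(events$energy[events$is_caloric]),
            class = c("recall_day", class(as_tibble(events))))
}

day_total <- function(day) {
  attr(day, "total_energy") %||% sum(day$energy[day$is_caloric])
}

#' Reconcile dual (or triple) data entries of one recall day
#'
#' Implements the dual-entry rule: when the CV between the two entries'
#' daily energy totals is at most 5%, the event-wise mean of the two is used;
#' when it exceeds 5%, a third entry is required and the pair with the best
#' agreement (lowest CV) is averaged. Ties prefer a pair containing the
#' third entry (the re-entered data). Event-wise averaging matches events by
#' within-day order and requires equal event counts — mismatched counts are
#' an error rather than a silent alignment.
#'
#' @param entry_a,entry_b Recall days ([as_recall_day()]) for the same
#'   participant-date from the two primary entries.
#' @param entry_c Optional third entry, required when `CV(a, b) > 5`.
#' @param cv_threshold Agreement threshold in percent (default 5).
#' @return A reconciled recall day; its total energy equals the mean of the
#'   chosen pair's totals.
#' @export
reconcile_dual_entry <- function(entry_a, entry_b, entry_c = NULL,
                                 cv_threshold = 5) {
  check_same_day(entry_a, entry_b)
  cv_ab <- energy_cv(day_total(entry_a), day_total(entry_b))
  if (cv_ab <= cv_threshold) {
    return(average_entries(entry_a, entry_b))
  }
  if (is.null(entry_c)) {
    abort(sprintf(
      "entries disagree (CV %.2f%% > %g%%) and no third entry is available",
      cv_ab, cv_threshold), class = "chronomeal_reconciliation_error")
  }
  check_same_day(entry_a, entry_c)
  cvs <- c(
    ab = cv_ab,
    ac = energy_cv(day_total(entry_a), day_total(entry_c)),
    bc = energy_cv(day_total(entry_b), day_total(entry_c))
  )
  # prefer pairs containing entry_c on ties
  order_pref <- c(ab = 2L, ac = 1L, bc = 1L)
  best <- names(cvs)[order(cvs, order_pref)][1]
  pair <- switch(best,
    ab = list(entry_a, entry_b),
    ac = list(entry_a, entry_c),
    bc = list(entry_b, entry_c)
  )
  average_entries(pair[[1]], pair[[2]])
}

check_same_day <- function(a, b) {
  same <- identical(as.character(a$participant_id[1]), as.character(b$participant_id[1])) &&
    identical(as.character(a$date[1]), as.character(b$date[1]))
  if (!same) {
    abort("entries refer to different participant-days",
          class = "chronomeal_reconciliation_error")
  }
}

average_entries <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    abort(sprintf(
      "cannot average entries with different event counts (%d vs %d)",
      nrow(a), nrow(b)), class = "chronomeal_reconciliation_error")
  }
  out <- a
  out$day_hour <- (a$day_hour + b$day_hour) / 2
  out$clock_time <- out$day_hour %% 24
  out$energy <- (a$energy + b$energy) / 2
  out$is_caloric <- a$is_caloric | b$is_caloric
  out$entry_id <- NA_character_
  as_recall_day(as_tibble(out))
}

#' Split raw events into reconciled recall days
#'
#' Groups an event table into participant-days. Days carrying `entry_id`
#' values are reconciled with [reconcile_dual_entry()]; days without are
#' passed through [as_recall_day()] directly.
#'
#' @param events Event tibble from [read_recall_table()].
#' @param cv_threshold Passed to [reconcile_dual_entry()].
#' @return A list of recall days.
#' @export
build_recall_days <- function(events, cv_threshold = 5) {
  keys <- paste(events$participant_id, events$date, sep = "\r")
  split(events, keys) |>
    map(function(df) {
      ids <- unique(df$entry_id[!is.na(df$entry_id)])
      if (length(ids) < 2) {
        return(as_recall_day(df))
      }
      get_entry <- function(id) {
        sub <- df[!is.na(df$entry_id) & df$entry_id == id, , drop = FALSE]
        if (nrow(sub) == 0) NULL else as_recall_day(sub)
      }
      reconcile_dual_entry(get_entry("A"), get_entry("B"), get_entry("C"),
                           cv_threshold = cv_threshold)
    }) |>
    unname()
}
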