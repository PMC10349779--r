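# Fixture builders used across the test files. Everything is constructed in
# code; no data files.

make_events <- function(times, energies, pid = "P1", date = "2015-10-13",
                        day_type = "working", labels = NA_character_,
                        entry_id = NA_character_, day_start = 4) {
  tibble::tibble(
    participant_id = pid,
    date = as.Date(date),
    day_type = day_type,
    clock_time = times %% 24,
    energy = energies,
    meal_label = labels,
    entry_id = entry_id,
    day_hour = chronomeal::within_day_axis(times, day_start),
    is_caloric = energies > 0
  )
}

make_day <- function(times, energies, ...) {
  chronomeal::as_recall_day(make_events(times, energies, ...))
}

make_nights <- function(onsets, offsets, wear = 20,
                        day_types = NULL, pid = "P1") {
  n <- length(onsets)
  if (is.null(day_types)) {
    day_types <- c(rep("working", 5), rep("non-working", 2))[seq_len(n)]
  }
  on_na <- chronomeal::to_noon_axis(onsets)
  off_na <- chronomeal::to_noon_axis(offsets)
  off_na <- ifelse(off_na <= on_na, off_na + 24, off_na)
  tibble::tibble(
    participant_id = pid,
    date = as.Date("2015-10-05") + seq_len(n) - 1,
    day_type = day_types,
    onset = on_na,
    offset = off_na,
    wear_hours = rep_len(wear, n),
    duration = off_na - on_na
  )
}

# A small, fully in-memory participant table with plausible values.
make_participants <- function(n = 8, seed = 99) {
  withr::with_seed(seed, {
    tibble::tibble(
      participant_id = sprintf("P%d", seq_len(n)),
      sex = rep(c("man", "woman"), length.out = n),
      age = round(runif(n, 19, 25), 1),
      weight_kg = rnorm(n, 72, 10),
      height_cm = rnorm(n, 170, 7),
      waist_cm = rnorm(n, 82, 9),
      sbp_1 = rnorm(n, 118, 8), sbp_2 = rnorm(n, 118, 8),
      sbp_3 = rnorm(n, 118, 8),
      dbp_1 = rnorm(n, 71, 5), dbp_2 = rnorm(n, 71, 5),
      dbp_3 = rnorm(n, 71, 5),
      glucose = rnorm(n, 87, 6),
      insulin = runif(n, 4, 12),
      triglycerides = runif(n, 50, 150),
      total_chol = rnorm(n, 160, 20),
      hdl = rnorm(n, 51, 8),
      med_diet_score = runif(n, 4, 12),
      light_pa_min = runif(n, 60, 200)
    )
  })
}
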