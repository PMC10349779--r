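test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 1), "n_participants",
               class = "chronomeal_config_error")
  expect_error(cohort_config(fraction_women = 1.2), "fraction_women",
               class = "chronomeal_config_error")
  expect_error(cohort_config(breakfast_skip_prob = -0.1),
               "breakfast_skip_prob", class = "chronomeal_config_error")
  expect_error(cohort_config(dual_entry_cv_sd = -1), "dual_entry_cv_sd",
               class = "chronomeal_config_error")
  expect_error(
    cohort_config(marginals = cohort_marginals(
      sleep = list(night_jitter_sd = -0.5))),
    "night_jitter_sd", class = "chronomeal_config_error")
  # a 4-participant cohort must keep 2 per sex
  expect_error(cohort_config(n_participants = 4, fraction_women = 0.9),
               "fraction_women", class = "chronomeal_config_error")
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- cohort_config(n_participants = 10, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recall_events, c2$recall_events)
  expect_identical(c1$sleep_nights, c2$sleep_nights)
  expect_identical(c1$participants, c2$participants)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort_csvs(c1, d1); write_cohort_csvs(c2, d2)
  for (f in c("recalls.csv", "sleep.csv", "participants.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed gives different draws
  c3 <- generate_cohort(cohort_config(n_participants = 10, seed = 8))
  expect_false(identical(c1$recall_events, c3$recall_events))
})

test_that("every participant has 3 recall days (2+1) and 7 nights (5+2)", {
  cohort <- generate_cohort(cohort_config(n_participants = 30, seed = 3))
  days <- dplyr::distinct(cohort$recall_events, participant_id, date, day_type)
  per <- dplyr::count(days, participant_id, day_type)
  expect_true(all(per$n[per$day_type == "working"] == 2))
  expect_true(all(per$n[per$day_type == "non-working"] == 1))
  expect_equal(nrow(dplyr::distinct(days, participant_id)), 30)

  nights <- dplyr::count(cohort$sleep_nights, participant_id, day_type)
  expect_true(all(nights$n[nights$day_type == "working"] == 5))
  expect_true(all(nights$n[nights$day_type == "non-working"] == 2))

  # events ordered in time within each participant-day
  ord <- cohort$recall_events |>
    dplyr::group_by(participant_id, date) |>
    dplyr::summarise(sorted = !is.unsorted(day_hour), .groups = "drop")
  expect_true(all(ord$sorted))

  # truth records exactly the planted slopes
  expect_equal(cohort$truth$beta_std, c(-0.605, 0.485, 0, 0))
})

test_that("weekly eating window marginal matches its configured target", {
  cohort <- generate_cohort(cohort_config(n_participants = 4000, seed = 2))
  expect_lt(abs(mean(cohort$derived$eating_window) - 12.10), 0.2)
  expect_lt(abs(mean(cohort$derived$msp_to_first) - 4.87), 0.2)
})

test_that("planted slopes are recovered by refitting on the generated data", {
  cfg <- cohort_config(n_participants = 700, fraction_women = 0.5, seed = 9)
  cohort <- generate_cohort(cfg)
  an <- transform_outcomes(
    dplyr::left_join(build_biomarker_panel(cohort$participants),
                     cohort$derived, by = "participant_id"))
  men <- an[an$sex == "man", ]
  women <- an[an$sex == "woman", ]
  expect_equal(simple_regression(men$eating_window, men$homa_ir)$beta_std,
               -0.605, tolerance = 0.02)
  expect_equal(simple_regression(men$msp_to_first, men$homa_ir)$beta_std,
               0.485, tolerance = 0.03)
  expect_lt(abs(simple_regression(women$eating_window, women$homa_ir)$beta_std),
            0.1)
})

test_that("HOMA identity holds exactly in the generated panel", {
  cohort <- generate_cohort(cohort_config(n_participants = 50, seed = 5))
  p <- cohort$participants
  expect_equal(homa_ir(p$glucose, p$insulin),
               p$glucose * p$insulin / 405)
  expect_true(all(p$insulin > 0))
})

test_that("dual entries: zero noise gives identical pairs and no thirds", {
  cfg <- cohort_config(n_participants = 6, seed = 4, dual_entry_cv_sd = 0)
  cohort <- generate_cohort(cfg)
  dual <- emit_dual_entries(cohort, cfg)
  expect_setequal(unique(dual$entry_id), c("A", "B"))
  totals <- dual |>
    dplyr::group_by(participant_id, date, entry_id) |>
    dplyr::summarise(total = sum(energy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = entry_id, values_from = total)
  expect_equal(totals$A, totals$B)
})

test_that("dual entries draw the configured CV and add thirds above 5%", {
  cfg <- cohort_config(n_participants = 40, seed = 6, dual_entry_cv_sd = 6)
  cohort <- generate_cohort(cfg)
  dual <- emit_dual_entries(cohort, cfg)
  totals <- dual |>
    dplyr::group_by(participant_id, date, entry_id) |>
    dplyr::summarise(total = sum(energy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = entry_id, values_from = total)
  cv_ab <- mapply(energy_cv, totals$A, totals$B)
  has_c <- !is.na(totals$C)
  expect_equal(has_c, cv_ab > 5)
  expect_true(any(has_c))
  expect_true(any(!has_c))

  # reconciliation consumes the fixture: totals equal the best pair's mean
  days <- build_recall_days(dual)
  expect_length(days, 40 * 3)
  rec_totals <- vapply(days, attr, numeric(1), "total_energy")
  expect_true(all(rec_totals > 0))
})

test_that("the dual-entry scaling factor realizes the drawn CV exactly", {
  k <- chronomeal:::cv_to_ratio(6.734)
  expect_equal(energy_cv(100, 100 * k), 6.734)
  expect_equal(chronomeal:::cv_to_ratio(0), 1)
})
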