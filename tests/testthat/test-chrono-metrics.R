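test_that("daily eating window spans first to last caloric intake", {
  expect_equal(daily_eating_window(make_day(c(8, 20.5), c(400, 600))), 12.5)
  expect_equal(daily_eating_window(make_day(9, 500)), 0)
  # a 00:30 event belongs to the evening of the same recall day
  expect_equal(daily_eating_window(make_day(c(10, 0.5), c(400, 200))), 14.5)
  # non-caloric events are ignored
  d <- make_day(c(7, 9, 21), c(0, 400, 600))
  expect_equal(daily_eating_window(d), 12)
  expect_true(is.na(daily_eating_window(make_day(9, 0))))
})

test_that("caloric midpoint is where cumulative energy first reaches half", {
  expect_equal(daily_caloric_midpoint(make_day(9, 500)), 9)
  expect_equal(
    daily_caloric_midpoint(make_day(c(8, 13, 20), c(300, 300, 300))), 13)
  expect_equal(
    daily_caloric_midpoint(make_day(c(8, 13, 20), c(500, 100, 100))), 8)
})

test_that("caloric midpoint never leaves the eating window", {
  withr::with_seed(21, {
    for (i in 1:30) {
      k <- sample(2:6, 1)
      times <- sort(runif(k, 6, 26))
      day <- make_day(times, runif(k, 50, 800))
      mid <- daily_caloric_midpoint(day, clock = FALSE)
      expect_gte(mid, min(day$day_hour))
      expect_lte(mid, max(day$day_hour))
    }
  })
})

test_that("eating midpoint is the temporal middle of the window", {
  expect_equal(daily_eating_midpoint(make_day(c(8, 20), c(1, 1))), 14)
  expect_equal(daily_eating_midpoint(make_day(9, 100)), 9)
  expect_equal(
    daily_eating_midpoint(make_day(c(10, 0.5), c(1, 1)), clock = FALSE),
    (10 + 24.5) / 2)
})

test_that("eating jetlag is signed non-working minus working", {
  expect_equal(eating_jetlag(15, 13.8), 1.2)
  expect_equal(eating_jetlag(14, 14), 0)
  expect_equal(eating_jetlag(13, 14.5), -1.5)
  expect_true(is.na(eating_jetlag(NA, 14)))
})

test_that("midsleep-anchored intervals reproduce the published composition", {
  msp <- 5 + 4 / 60            # 05:04
  first <- 9 + 56 / 60         # 09:56
  last <- 22 + 1 / 60          # 22:01
  expect_equal(round(msp_to_first_intake(first, msp), 2), 4.87)
  expect_equal(round(last_intake_to_msp(last, msp), 2), 7.05)
  expect_equal(msp_to_first_intake(4 + 3, 4), 3)
  expect_equal(last_intake_to_msp(5 - 8, 5), 8)
  # implausible orderings surface as near-24 values for QC, not negatives
  expect_equal(msp_to_first_intake(4, 5), 23)
  expect_equal(last_intake_to_msp(6, 5), 23)
})

test_that("per-day closure identity is exact under shared midsleep", {
  withr::with_seed(31, {
    for (i in 1:20) {
      msp <- runif(1, 3, 7)
      first <- msp + runif(1, 1, 8)
      last <- first + runif(1, 2, 14)
      total <- msp_to_first_intake(first %% 24, msp) +
        (last - first) +
        last_intake_to_msp(last %% 24, msp)
      expect_equal(total, 24)
    }
  })
})

test_that("breakfast classification follows the three-recall rule", {
  consumer_days <- lapply(1:3, function(i) make_day(c(8.5, 14, 21), c(300, 700, 600),
                                                    date = sprintf("2015-10-%02d", 12 + i)))
  expect_equal(classify_breakfast(consumer_days), "consumer")

  late <- consumer_days
  late[[2]] <- make_day(c(13, 21), c(700, 600), date = "2015-10-14")
  expect_equal(classify_breakfast(late), "skipper")

  tiny <- lapply(1:3, function(i) make_day(c(7, 14, 21), c(20, 700, 600),
                                           date = sprintf("2015-10-%02d", 12 + i)))
  expect_equal(classify_breakfast(tiny), "skipper")
  expect_equal(classify_breakfast(tiny, min_kcal = 10), "consumer")

  # an explicitly labelled breakfast overrides the clock rule
  labelled <- lapply(1:3, function(i) {
    make_day(c(12.5, 21), c(400, 600), labels = c("breakfast", "dinner"),
             date = sprintf("2015-10-%02d", 12 + i))
  })
  expect_equal(classify_breakfast(labelled), "consumer")

  expect_error(classify_breakfast(consumer_days[1:2]),
               class = "chronomeal_classification_error")
})

test_that("vectorized weekly profile matches the per-day operations", {
  withr::with_seed(41, {
    days <- list(
      make_day(sort(runif(4, 8, 22)), runif(4, 100, 700),
               date = "2015-10-13", day_type = "working"),
      make_day(sort(runif(3, 7, 21)), runif(3, 100, 700),
               date = "2015-10-21", day_type = "working"),
      make_day(sort(runif(5, 9, 23)), runif(5, 100, 700),
               date = "2015-10-25", day_type = "non-working")
    )
  })
  nights <- make_nights(c(rep(0.5, 5), rep(1.5, 2)), c(rep(8, 5), rep(9.5, 2)))
  ss <- weekly_sleep_summary(nights)
  prof <- weekly_chrono_profile(days, ss)

  win <- vapply(days, daily_eating_window, numeric(1))
  emid <- vapply(days, daily_eating_midpoint, numeric(1), clock = FALSE)
  cmid <- vapply(days, daily_caloric_midpoint, numeric(1), clock = FALSE)
  firsts <- vapply(days, function(d) min(d$day_hour[d$is_caloric]), numeric(1))

  expect_equal(prof$eating_window,
               weighted_week_mean(mean(win[1:2]), win[3]))
  expect_equal(prof$caloric_midpoint,
               weighted_week_mean(mean(cmid[1:2]), cmid[3]) %% 24)
  expect_equal(prof$eating_jetlag, emid[3] - mean(emid[1:2]))
  expect_equal(prof$msp_to_first,
               msp_to_first_intake(
                 weighted_week_mean(mean(firsts[1:2]), firsts[3]) %% 24,
                 ss$midsleep_week))
})

test_that("participants without valid sleep keep recall metrics only", {
  days <- list(make_day(c(8, 13, 20), c(300, 700, 600), date = "2015-10-13"),
               make_day(c(8, 13, 20), c(300, 700, 600), date = "2015-10-21"),
               make_day(c(9, 14, 21), c(300, 700, 600), date = "2015-10-25",
                        day_type = "non-working"))
  bad_nights <- make_nights(rep(0, 7), rep(8, 7), wear = 10)
  ss <- weekly_sleep_summary(bad_nights)
  prof <- weekly_chrono_profile(days, ss)
  expect_false(is.na(prof$eating_window))
  expect_true(is.na(prof$msp_to_first))
  expect_true(is.na(prof$last_to_msp))
})
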