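test_that("zero-noise simulation puts every onset at the configured mean", {
  p <- zero_noise_profile(mean_onset = "23:30", mean_offset = "07:30")
  sim <- simulate_participant(p, n_days = 4, seed = 1, off_wrist_prob = 0,
                              diary_missing_prob = 0)
  expect_true(all(sim$truth$true_onset == parse_clock("23:30")))
  expect_true(all(sim$truth$true_offset == parse_clock("07:30")))
  expect_false(any(sim$truth$sleepless))
})

test_that("simulation is a pure function of the seed", {
  p <- default_community_profiles()$tent.winter
  a <- simulate_participant(p, n_days = 3, seed = 99)
  b <- simulate_participant(p, n_days = 3, seed = 99)
  expect_identical(a$series$activity, b$series$activity)
  expect_identical(a$series$lux, b$series$lux)
  expect_identical(a$diary, b$diary)
  expect_identical(a$truth, b$truth)
  c <- simulate_participant(p, n_days = 3, seed = 100)
  expect_false(identical(a$series$activity, c$series$activity))
})

test_that("within-person timing SD is recovered by Monte Carlo", {
  p <- community_profile("housed", "winter", "23:30", "07:30",
                         between_person_sd = 0, within_person_sd = 30,
                         sleep_activity_mean = 10)
  sim <- simulate_participant(p, n_days = 1000, seed = 4, off_wrist_prob = 0)
  onsets_nm <- noon_minutes(sim$truth$true_onset)
  expect_equal(sd(onsets_nm), 30, tolerance = 2)
})

test_that("generated series satisfy the epoch-series invariants", {
  for (g in c("tent.summer", "overnight_shelter.winter")) {
    p <- default_community_profiles()[[g]]
    sim <- simulate_participant(p, n_days = 3, seed = 11)
    s <- sim$series
    expect_s3_class(s, "epoch_series")
    expect_true(all(s$activity >= 0, na.rm = TRUE))
    expect_true(all(s$lux >= 0, na.rm = TRUE))
    expect_equal(length(s$activity), length(s$lux))
    expect_equal(length(s$activity), length(s$off_wrist))
    expect_equal(nrow(sim$truth), 3)  # truth exists for every night
  }
})

test_that("cohort generation honours counts, seeding, and insertion order", {
  cc1 <- cohort_config(c(tent.winter = 5, housed.winter = 5), n_days = 2)
  cc2 <- cohort_config(c(housed.winter = 5, tent.winter = 5), n_days = 2)
  a <- generate_cohort(cc1, seed = 3)
  b <- generate_cohort(cc2, seed = 3)
  expect_equal(sum(a$roster$community == "tent"), 5)
  expect_equal(sum(a$roster$community == "housed"), 5)
  # insertion order of the config does not change the cohort
  expect_identical(a$roster[order(a$roster$participant_id), ],
                   b$roster[order(b$roster$participant_id), ])
  expect_identical(a$series[["tent.winter_03"]]$activity,
                   b$series[["tent.winter_03"]]$activity)
  # same master seed, same cohort
  expect_identical(generate_cohort(cc1, seed = 3)$truth, a$truth)
  expect_error(generate_cohort(cohort_config(c(tent.spring = 1))),
               "no profile")
})

test_that("sleepless-night rate matches the binomial law", {
  p <- community_profile("tent", "winter", "23:30", "07:30",
                         between_person_sd = 30, within_person_sd = 30,
                         sleepless_prob = 0.1, sleep_activity_mean = 20)
  n_nights <- 0; n_sleepless <- 0
  for (s in 1:25) {
    sim <- simulate_participant(p, n_days = 80, seed = 1000 + s)
    n_nights <- n_nights + nrow(sim$truth)
    n_sleepless <- n_sleepless + sum(sim$truth$sleepless)
  }
  expect_equal(n_nights, 2000)
  ci <- qbinom(c(0.005, 0.995), n_nights, 0.1)
  expect_gte(n_sleepless, ci[1])
  expect_lte(n_sleepless, ci[2])
})

test_that("sleepless nights have wake-like activity and no diary entry", {
  p <- community_profile("tent", "winter", "23:30", "07:30",
                         between_person_sd = 0, within_person_sd = 0,
                         sleepless_prob = 0.5, sleep_activity_mean = 20)
  sim <- simulate_participant(p, n_days = 20, seed = 8, off_wrist_prob = 0,
                              diary_missing_prob = 0)
  sl <- sim$truth$sleepless
  expect_true(any(sl) && any(!sl))
  expect_true(all(is.na(sim$truth$true_onset[sl])))
  expect_false(any(sim$diary$date %in% sim$truth$night_date[sl]))
  # overnight activity on a sleepless night stays at waking levels
  mod <- epoch_minute_of_day(sim$series)
  dts <- epoch_date(sim$series)
  for (d in sim$truth$night_date[sl][1:2]) {
    night_idx <- (dts == d & mod >= 23.5 * 60) | (dts == d + 1 & mod < 420)
    expect_gt(mean(sim$series$activity[night_idx], na.rm = TRUE), 100)
  }
})

test_that("higher light transmission never shortens time above any threshold", {
  base <- default_community_profiles()$tent.winter
  trans <- c(0.1, 0.3, 0.6, 0.9)
  for (thr in c(50, 200, 1000)) {
    durs <- vapply(trans, function(tr) {
      p <- base; p$light_transmission <- tr
      sim <- simulate_participant(p, n_days = 4, seed = 21, off_wrist_prob = 0)
      mean(daily_light_metrics(sim$series, threshold = thr)$duration)
    }, numeric(1))
    expect_true(all(diff(durs) >= 0))
  }
})
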