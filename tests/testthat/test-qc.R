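diary_row <- function(id = "p1", date = "2023-01-09", bedtime = NA,
                      waketime = NA, location = NA) {
  data.frame(participant_id = id, date = as.Date(date),
             bedtime = if (is.character(bedtime)) parse_clock(bedtime) else bedtime,
             waketime = if (is.character(waketime)) parse_clock(waketime) else waketime,
             location = location, stringsAsFactors = FALSE)
}

test_that("diary discrepancy uses circular gaps with a strict 3-h bound", {
  # watch onset 23:00 vs reported 02:30 -> 3.5 h -> excluded
  n <- make_night(onset = parse_clock("23:00"), offset = parse_clock("07:00"))
  d <- diary_row(bedtime = "02:30", waketime = "07:00")
  expect_true(crosscheck_night_with_diary(n, d)$excluded)
  expect_equal(crosscheck_night_with_diary(n, d)$exclusion_reason,
               "diary_discrepancy")
  # exactly 3 h is kept (strict inequality)
  d3 <- diary_row(bedtime = "02:00", waketime = "07:00")
  expect_false(crosscheck_night_with_diary(n, d3)$excluded)
  # no diary entry that date -> kept
  d_other <- diary_row(date = "2023-01-10", bedtime = "02:30")
  expect_false(crosscheck_night_with_diary(n, d_other)$excluded)
  # missing fields -> kept
  expect_false(crosscheck_night_with_diary(n, diary_row())$excluded)
  # circularity: 23:50 watch vs 00:10 diary is 20 min, not 23 h 40
  n2 <- make_night(onset = parse_clock("23:50"), offset = parse_clock("07:00"))
  d2 <- diary_row(bedtime = "00:10", waketime = "07:00")
  expect_false(crosscheck_night_with_diary(n2, d2)$excluded)
})

test_that("off-site nights are excluded, unmapped locations kept and listed", {
  roster <- roster_row("p1", community = "tent")
  n <- make_night()
  out <- filter_offsite_nights(n, diary_row(location = "hotel"), roster)
  expect_true(out$excluded)
  expect_equal(out$exclusion_reason, "offsite")
  expect_false(filter_offsite_nights(n, diary_row(location = "tent"),
                                     roster)$excluded)
  expect_false(filter_offsite_nights(n, diary_row(), roster)$excluded)
  out2 <- filter_offsite_nights(n, diary_row(location = "yurt"), roster)
  expect_false(out2$excluded)
  expect_equal(attr(out2, "unmapped_locations"), "yurt")
})

test_that("participant inclusion enforces the 14-night minimum and shift work", {
  mk <- function(id, n, excl = 0) {
    do.call(rbind, lapply(seq_len(n), function(i)
      make_night(id, as.Date("2023-01-01") + i,
                 excluded = i <= excl,
                 reason = if (i <= excl) "offsite" else "none")))
  }
  nights <- rbind(mk("p13", 13), mk("p14", 14), mk("p20", 20, excl = 7),
                  mk("shift", 20))
  roster <- rbind(roster_row("p13"), roster_row("p14"), roster_row("p20"),
                  roster_row("shift", shift_work = TRUE))
  res <- apply_participant_inclusion(nights, roster)
  expect_equal(sort(res$roster$participant_id), c("p14"))
  ex <- res$report$excluded_participants
  expect_setequal(ex$participant_id, c("p13", "p20", "shift"))
  expect_equal(ex$reason[ex$participant_id == "shift"], "shift_work")
  expect_equal(ex$reason[ex$participant_id == "p13"], "too_few_nights")
  # boundary: exactly 14 surviving nights is included
  expect_true("p14" %in% res$roster$participant_id)
})

test_that("sleepless nights count toward the participant minimum", {
  nights <- do.call(rbind, lapply(1:14, function(i)
    make_night("p1", as.Date("2023-01-01") + i, sleepless = i <= 6)))
  res <- apply_participant_inclusion(nights, roster_row("p1"))
  expect_true("p1" %in% res$roster$participant_id)
})

test_that("exclusion counts reconcile with total nights", {
  cc <- cohort_config(c(tent.winter = 3), n_days = 18)
  cohort <- generate_cohort(cc, seed = 17)
  nights <- do.call(rbind, lapply(cohort$series, score_nights))
  nights <- flag_sleepless_nights(nights, cohort$diary)
  qc <- qc_nights(nights, cohort$diary, cohort$roster)
  nc <- qc$report$night_counts
  expect_equal(nc$surviving + nc$diary_discrepancy + nc$offsite +
                 nc$missing_data, nc$total_nights)
})

test_that("the full QC is idempotent and night filters commute", {
  cc <- cohort_config(c(tent.winter = 2, housed.winter = 2), n_days = 18)
  cohort <- generate_cohort(cc, seed = 29)
  nights <- do.call(rbind, lapply(cohort$series, score_nights))
  nights <- flag_sleepless_nights(nights, cohort$diary)
  rownames(nights) <- NULL
  qc1 <- qc_nights(nights, cohort$diary, cohort$roster, min_nights = 10)
  qc2_in <- qc1$nights
  qc2 <- qc_nights(qc2_in, cohort$diary, cohort$roster, min_nights = 10)
  expect_equal(qc2$nights$excluded, qc2_in$excluded)
  expect_equal(qc2$nights$exclusion_reason, qc2_in$exclusion_reason)
  expect_equal(qc2$roster$participant_id, qc1$roster$participant_id)
  # order of night-level filters does not change the surviving set
  a <- filter_offsite_nights(
    crosscheck_night_with_diary(nights, cohort$diary),
    cohort$diary, cohort$roster)
  b <- crosscheck_night_with_diary(
    filter_offsite_nights(nights, cohort$diary, cohort$roster),
    cohort$diary)
  expect_equal(a$excluded, b$excluded)
})
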