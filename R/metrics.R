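#' Per-participant sleep metrics
#'
#' Circular timing means and SDs, arithmetic duration statistics, the Sleep
#' Regularity Index, and mean in-sleep activity — one value per participant,
#' averaged over that participant's QC-surviving nights.
#'
#' @name sleep_metrics
NULL

#' Day-by-epoch sleep/wake state matrix
#'
#' Reshapes a scored 60-s recording into a matrix of civil days (rows) by
#' 1440 minutes-of-day (columns), TRUE = sleep. Off-wrist epochs and epochs
#' outside the recording are NA; nights listed in `mask_nights` have their
#' noon-to-noon day masked (used to drop QC-excluded nights from the SRI).
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param scored optional [score_epoch_sleep()] result.
#' @param params a [scoring_params()].
#' @param mask_nights optional Date vector of excluded night dates.
#' @return logical matrix, one row per civil day.
#' @export
state_matrix <- function(series, scored = NULL, params = scoring_params(),
                         mask_nights = NULL) {
  if (series$epoch_length != 60L) stop("state_matrix requires 60-s epochs")
  if (is.null(scored)) scored <- score_epoch_sleep(series, params)
  t0 <- as.numeric(series$start)
  day0 <- as.Date(series$start)
  offset_min <- round((t0 - as.numeric(as.POSIXct(paste(day0, "00:00:00"),
                                                  tz = "UTC"))) / 60)
  n_days <- ceiling((offset_min + length(series)) / MIN_PER_DAY)
  pos <- offset_min + seq_len(length(series))  # 1-based slot in the flat grid
  flat <- rep(NA, n_days * MIN_PER_DAY)
  flat[pos] <- scored
  m <- matrix(flat, nrow = n_days, ncol = MIN_PER_DAY, byrow = TRUE)
  rownames(m) <- as.character(day0 + seq_len(n_days) - 1L)
  if (!is.null(mask_nights)) {
    for (d in as.character(as.Date(mask_nights))) {
      i <- match(d, rownames(m))
      if (is.na(i)) next
      m[i, 721:MIN_PER_DAY] <- NA                      # noon to midnight
      if (i + 1 <= n_days) m[i + 1, 1:720] <- NA       # midnight to noon
    }
  }
  m
}

#' Sleep Regularity Index
#'
#' The probability of being in the same sleep/wake state at the same clock
#' time on consecutive days, rescaled so perfect regularity scores 100 and
#' total day-to-day disagreement scores -100:
#' `SRI = -100 + (200 / P) * sum over valid pairs of 1[state equal]`,
#' where a valid pair is (same minute-of-day, consecutive days, both states
#' observed) and P is the number of valid pairs.
#'
#' @param states matrix from [state_matrix()] (>= 2 rows).
#' @return SRI in `[-100, 100]`.
#' @export
sleep_regularity_index <- function(states) {
  if (!is.matrix(states) || nrow(states) < 2L) {
    stop("SRI needs a state matrix with at least 2 days")
  }
  a <- states[-nrow(states), , drop = FALSE]
  b <- states[-1, , drop = FALSE]
  valid <- !is.na(a) & !is.na(b)
  P <- sum(valid)
  if (P == 0L) stop("SRI undefined: no valid 24-h-apart state pairs")
  -100 + 200 * sum(a[valid] == b[valid]) / P
}

#' Summarise one participant's nights
#'
#' Timing parameters (onset, offset, midsleep) are averaged circularly and
#' their intraindividual SDs are circular SDs (linear SDs on the
#' noon-referenced scale are emitted alongside as `sd_*_linear`
#' diagnostics). Duration is arithmetic over non-sleepless nights —
#' sleepless nights are counted in `n_sleepless` but never enter
#' `mean_duration`. Excluded nights are ignored entirely.
#'
#' @param nights night records for one participant.
#' @param sri optional precomputed SRI for the participant.
#' @return one-row data.frame participant summary.
#' @export
participant_sleep_summary <- function(nights, sri = NA_real_) {
  stopifnot(length(unique(nights$participant_id)) == 1L)
  kept <- nights[!nights$excluded, , drop = FALSE]
  slept <- kept[!kept$sleepless, , drop = FALSE]
  n_slept <- nrow(slept)
  csd <- function(x) if (n_slept > 1) circular_sd_clock_time(x) else
    if (n_slept == 1) 0 else NA_real_
  cm <- function(x) if (n_slept > 0) circular_mean_clock_time(x) else NA_real_
  lsd <- function(x) if (n_slept > 1) stats::sd(noon_minutes(x)) else
    if (n_slept == 1) 0 else NA_real_
  data.frame(
    participant_id = nights$participant_id[1],
    n_nights = nrow(kept),
    n_sleepless = sum(kept$sleepless, na.rm = TRUE),
    mean_onset = cm(slept$onset),
    mean_offset = cm(slept$offset),
    mean_midsleep = cm(slept$midsleep),
    mean_duration = if (n_slept > 0) mean(slept$duration) else NA_real_,
    sd_onset = csd(slept$onset),
    sd_offset = csd(slept$offset),
    sd_midsleep = csd(slept$midsleep),
    sd_duration = if (n_slept > 1) stats::sd(slept$duration) else
      if (n_slept == 1) 0 else NA_real_,
    sd_onset_linear = lsd(slept$onset),
    sd_offset_linear = lsd(slept$offset),
    sd_midsleep_linear = lsd(slept$midsleep),
    sri = sri,
    mean_in_sleep_activity = if (n_slept > 0)
      mean(slept$in_sleep_activity, na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Mean activity during watch-determined sleep bouts
#'
#' Two-stage average: counts/min are averaged within each night's
#' `[onset, offset)` bout, then the nightly means are averaged — never a
#' pooled epoch mean, so long and short nights weigh equally.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param nights QC-filtered night records for this participant.
#' @return mean counts/min, or NA with no qualifying nights.
#' @export
activity_during_sleep <- function(series, nights) {
  ok <- !nights$excluded & !nights$sleepless & !is.na(nights$onset)
  nights <- nights[ok, , drop = FALSE]
  if (nrow(nights) == 0L) return(NA_real_)
  t0 <- as.numeric(series$start)
  nightly <- vapply(seq_len(nrow(nights)), function(i) {
    d0 <- as.numeric(as.POSIXct(paste(nights$night_date[i], "12:00:00"),
                                tz = "UTC"))
    on_abs <- d0 + noon_minutes(nights$onset[i]) * 60
    off_abs <- d0 + noon_minutes(nights$offset[i]) * 60
    if (off_abs <= on_abs) off_abs <- off_abs + 86400
    a <- floor((on_abs - t0) / 60) + 1
    b <- floor((off_abs - t0) / 60)
    a <- max(a, 1); b <- min(b, length(series))
    if (b < a) return(NA_real_)
    mean(series$activity[a:b], na.rm = TRUE)
  }, numeric(1))
  mean(nightly, na.rm = TRUE)
}
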