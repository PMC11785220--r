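#' Sleep-scoring parameters
#'
#' Constants of the open weighted-window wrist-actigraphy scorer and the
#' rest-interval detector. An epoch is scored sleep when the weighted sum of
#' its activity and that of its four nearest neighbours falls at or below
#' `wake_threshold`; the nightly rest interval is the longest low-activity
#' span in the night search window.
#'
#' @param weight_near weight for the +-1 min neighbours (default 0.2).
#' @param weight_far weight for the +-2 min neighbours (default 0.04).
#' @param wake_threshold score at or below which an epoch is sleep
#'   (default 40 counts).
#' @param immobile_run consecutive sleep-scored epochs required to anchor
#'   onset/offset (default 10).
#' @param rest_low_fraction fraction of the day's median smoothed activity
#'   defining candidate rest epochs (default 0.5).
#' @param min_rest_minutes minimum length of the main rest interval
#'   (default 160).
#' @param night_window_start,night_window_end clock bounds of the nightly
#'   search window (defaults 18:00 and 12:00 next day).
#' @param smooth_minutes width of the running mean used by the rest
#'   detector (default 10).
#' @param max_interrupt longest over-threshold interruption (minutes) the
#'   rest detector bridges inside a candidate span (default 20).
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(weight_near = 0.2, weight_far = 0.04,
                           wake_threshold = 40, immobile_run = 10,
                           rest_low_fraction = 0.5, min_rest_minutes = 160,
                           night_window_start = "18:00",
                           night_window_end = "12:00",
                           smooth_minutes = 10, max_interrupt = 20) {
  if (is.character(night_window_start)) night_window_start <- parse_clock(night_window_start)
  if (is.character(night_window_end)) night_window_end <- parse_clock(night_window_end)
  stopifnot(weight_near >= 0, weight_far >= 0, wake_threshold >= 0,
            immobile_run >= 1, min_rest_minutes >= immobile_run,
            rest_low_fraction > 0, smooth_minutes >= 1)
  structure(list(weight_near = weight_near, weight_far = weight_far,
                 wake_threshold = wake_threshold, immobile_run = immobile_run,
                 rest_low_fraction = rest_low_fraction,
                 min_rest_minutes = min_rest_minutes,
                 night_window_start = night_window_start,
                 night_window_end = night_window_end,
                 smooth_minutes = smooth_minutes,
                 max_interrupt = max_interrupt),
            class = "scoring_params")
}

shift_vec <- function(x, k) {
  n <- length(x)
  if (k > 0) c(rep(NA_real_, k), x[seq_len(n - k)])
  else if (k < 0) c(x[seq_len(n + k) - k], rep(NA_real_, -k))
  else x
}

#' Score each epoch sleep/wake by the weighted activity window
#'
#' Epoch t is sleep iff
#' `A_t + w1 (A_{t-1} + A_{t+1}) + w2 (A_{t-2} + A_{t+2}) <= wake_threshold`.
#' Missing neighbours contribute 0; an off-wrist (missing) centre epoch
#' scores NA.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param params a [scoring_params()].
#' @return logical vector, TRUE = sleep, NA = unscorable.
#' @export
score_epoch_sleep <- function(series, params = scoring_params()) {
  if (series$epoch_length != 60L) {
    stop("sleep scoring requires 60-s epochs; resample_epochs() first")
  }
  a <- series$activity
  z <- function(x) ifelse(is.na(x), 0, x)
  w <- z(a) +
    params$weight_near * (z(shift_vec(a, 1)) + z(shift_vec(a, -1))) +
    params$weight_far * (z(shift_vec(a, 2)) + z(shift_vec(a, -2)))
  out <- w <= params$wake_threshold
  out[is.na(a)] <- NA
  out
}

running_mean <- function(x, width) {
  # centered running mean over available (non-missing) values
  n <- length(x)
  half <- width %/% 2
  xm <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(xm)); cc <- c(0, cumsum(cnt))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1] - cs[lo]
  k <- cc[hi + 1] - cc[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Detect the main nightly rest interval
#'
#' Within the night search window (18:00 on `night_date` to 12:00 the next
#' day by default), finds the longest contiguous span whose 10-min smoothed
#' activity stays at or below `rest_low_fraction` times the median smoothed
#' activity of the whole recording, provided the span is at least
#' `min_rest_minutes` long. Ties break toward the earlier span. The
#' recording-wide median (rather than a day-local one) keeps the reference
#' anchored at waking activity even on nights when sleep fills most of the
#' surrounding day.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param params a [scoring_params()].
#' @param night_date civil date on which the night starts.
#' @param smoothed optional precomputed smoothed activity (recycled across
#'   nights by [score_nights()]).
#' @return list with `start`, `end` (1-based epoch indices, end exclusive)
#'   or NULL when no qualifying span exists.
#' @export
detect_main_rest_interval <- function(series, params, night_date,
                                      smoothed = NULL) {
  night_date <- as.Date(night_date)
  t0 <- as.numeric(series$start)
  day0 <- as.numeric(as.POSIXct(paste(night_date, "12:00:00"), tz = "UTC"))
  idx_of <- function(abs_sec) floor((abs_sec - t0) / 60) + 1
  n <- length(series)
  sm <- if (is.null(smoothed)) running_mean(series$activity,
                                            params$smooth_minutes) else smoothed
  med <- stats::median(sm, na.rm = TRUE)
  if (!is.finite(med)) return(NULL)
  thr <- params$rest_low_fraction * med
  # window: night_window_start on night_date to night_window_end next day
  w_lo <- max(idx_of(day0 - 43200 + params$night_window_start * 60), 1)
  w_hi <- min(idx_of(day0 + 43200 + params$night_window_end * 60) - 1, n)
  if (w_lo > w_hi) return(NULL)
  cand <- sm[w_lo:w_hi] <= thr
  cand[is.na(cand)] <- FALSE
  # bridge brief over-threshold interruptions (restless stretches) so one
  # noisy window cannot split the night's rest span in two
  r0 <- rle(cand)
  interior <- seq_along(r0$values) > 1 & seq_along(r0$values) < length(r0$values)
  r0$values[!r0$values & interior & r0$lengths <= params$max_interrupt] <- TRUE
  cand <- inverse.rle(r0)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= params$min_rest_minutes
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.max(r$lengths[ok])]  # which.max takes the first tie
  list(start = w_lo + starts[best] - 1L, end = w_lo + ends[best],
       night_date = night_date)
}

night_record <- function(participant_id, night_date, onset = NA_real_,
                         offset = NA_real_, in_sleep_activity = NA_real_,
                         sleepless = NA, excluded = FALSE,
                         exclusion_reason = "none") {
  duration <- if (is.na(onset) || is.na(offset)) NA_real_ else
    (offset - onset) %% MIN_PER_DAY
  data.frame(
    participant_id = participant_id, night_date = as.Date(night_date),
    onset = onset, offset = offset, duration = duration,
    midsleep = if (is.na(duration)) NA_real_ else night_midsleep(onset, duration),
    sleepless = sleepless, excluded = excluded,
    exclusion_reason = exclusion_reason,
    in_sleep_activity = in_sleep_activity,
    stringsAsFactors = FALSE
  )
}

#' Score one night into a night record
#'
#' Onset is the start of the first run of `immobile_run` consecutive
#' sleep-scored epochs inside the rest interval; offset is the end of the
#' last such run. A night with no qualifying run comes back as a sleepless
#' candidate (`sleepless = NA`), resolved against the diary by
#' [flag_sleepless_nights()].
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param interval result of [detect_main_rest_interval()] (may be NULL).
#' @param params a [scoring_params()].
#' @param night_date civil date on which the night starts (used when
#'   `interval` is NULL).
#' @param sleep_scored optional precomputed [score_epoch_sleep()] vector.
#' @return one-row data.frame night record.
#' @export
score_night <- function(series, interval, params = scoring_params(),
                        night_date = NULL, sleep_scored = NULL) {
  pid <- series$participant_id
  if (is.null(interval)) {
    return(night_record(pid, night_date, sleepless = NA))
  }
  if (is.null(sleep_scored)) sleep_scored <- score_epoch_sleep(series, params)
  # the smoothed detector blurs interval edges by about half a smoothing
  # window, so the run search is padded by smooth_minutes on each side
  pad <- params$smooth_minutes
  idx <- max(interval$start - pad, 1L):min(interval$end - 1L + pad,
                                           length(series))
  s <- sleep_scored[idx]
  s[is.na(s)] <- FALSE
  r <- rle(s)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= params$immobile_run
  if (!any(ok)) {
    return(night_record(pid, interval$night_date, sleepless = NA))
  }
  first <- which(ok)[1]; last <- which(ok)[length(which(ok))]
  on_idx <- idx[starts[first]]            # first epoch of the onset run
  off_idx <- idx[ends[last]] + 1L         # one past the last sleep epoch
  minute0 <- (as.numeric(series$start) %% 86400) / 60
  clock_of <- function(i) (minute0 + (i - 1L)) %% MIN_PER_DAY
  bout <- series$activity[on_idx:(off_idx - 1L)]
  night_record(pid, interval$night_date,
               onset = clock_of(on_idx), offset = clock_of(off_idx),
               in_sleep_activity = mean(bout, na.rm = TRUE),
               sleepless = FALSE)
}

#' Score every night of a recording
#'
#' One night per civil date from the first to the penultimate date of the
#' recording (a night spans `date` 18:00 to `date + 1` 12:00).
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param params a [scoring_params()].
#' @return data.frame of night records, one row per night date.
#' @export
score_nights <- function(series, params = scoring_params()) {
  if (series$epoch_length != 60L) {
    stop("sleep scoring requires 60-s epochs; resample_epochs() first")
  }
  dates <- epoch_date(series)
  nights <- seq(min(dates), max(dates) - 1L, by = "day")
  scored <- score_epoch_sleep(series, params)
  sm <- running_mean(series$activity, params$smooth_minutes)
  out <- lapply(nights, function(d) {
    iv <- detect_main_rest_interval(series, params, d, smoothed = sm)
    score_night(series, iv, params, night_date = d, sleep_scored = scored)
  })
  do.call(rbind, out)
}

#' Resolve sleepless-candidate nights against the diary
#'
#' A night with no detected sleep and no diary entry for that date is a
#' sleepless night; with a diary entry present it is excluded as missing
#' data instead (the person reported sleep the watch did not detect).
#'
#' @param nights data.frame from [score_nights()].
#' @param diary diary data.frame ([read_diary_csv()] layout, clock minutes).
#' @return `nights` with `sleepless`/`excluded` resolved.
#' @export
flag_sleepless_nights <- function(nights, diary) {
  cand <- is.na(nights$sleepless)
  key <- paste(nights$participant_id, nights$night_date)
  dkey <- paste(diary$participant_id, diary$date)
  has_entry <- key %in% dkey
  nights$sleepless[cand & !has_entry] <- TRUE
  nights$excluded[cand & has_entry] <- TRUE
  nights$exclusion_reason[cand & has_entry] <- "missing_data"
  nights$sleepless[cand & has_entry] <- FALSE
  nights
}
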