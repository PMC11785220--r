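#' 24-h activity waveforms
#'
#' Raw 1-min counts are averaged into 48 half-hour bins per day,
#' log10(x + 1)-transformed, smoothed by a one-hour (3-bin) centered running
#' mean that wraps across midnight, and finally averaged across days into
#' one 48-bin profile per participant.
#'
#' @name waveforms
NULL

WAVEFORM_BINS <- 48L

wrap_running_mean3 <- function(x) {
  n <- length(x)
  (x + x[c(n, seq_len(n - 1))] + x[c(seq_len(n - 1) + 1, 1)]) / 3
}

#' Individual 24-h activity waveform
#'
#' @param series an [epoch_series()] at 60-s epochs covering >= 1 full civil
#'   day.
#' @return numeric vector of 48 smoothed log10-activity values; bin 1 starts
#'   at 00:00.
#' @export
participant_waveform <- function(series) {
  if (series$epoch_length != 60L) {
    stop("waveforms require 60-s epochs; resample_epochs() first")
  }
  mod <- epoch_minute_of_day(series)
  dates <- epoch_date(series)
  full <- names(which(table(dates) == MIN_PER_DAY))
  if (length(full) < 1L) stop("need at least one full civil day of data")
  keep <- dates %in% as.Date(full)
  bin <- floor(mod[keep] / 30) + 1L
  day <- as.character(dates[keep])
  profiles <- vapply(unique(day), function(d) {
    sel <- day == d
    binned <- tapply(series$activity[keep][sel], bin[sel],
                     mean, na.rm = TRUE)
    v <- as.numeric(binned)[order(as.integer(names(binned)))]
    v[is.nan(v)] <- NA_real_
    lv <- log10(v + 1)
    if (anyNA(lv)) lv[is.na(lv)] <- mean(lv, na.rm = TRUE)  # rare off-wrist bins
    wrap_running_mean3(lv)
  }, numeric(WAVEFORM_BINS))
  rowMeans(profiles, na.rm = TRUE)
}

#' Community mean waveform with per-bin SEM
#'
#' @param waveforms list (or 48-row matrix) of individual waveforms.
#' @return data.frame with `bin_start_min`, `mean`, `sem` (NA when n = 1).
#' @export
community_waveform <- function(waveforms) {
  m <- if (is.list(waveforms)) do.call(cbind, waveforms) else as.matrix(waveforms)
  if (nrow(m) != WAVEFORM_BINS) stop("waveforms must have 48 bins")
  n <- ncol(m)
  data.frame(
    bin_start_min = (seq_len(WAVEFORM_BINS) - 1L) * 30,
    mean = rowMeans(m),
    sem = if (n >= 2) apply(m, 1, stats::sd) / sqrt(n) else NA_real_
  )
}

#' Season-specific morning/evening comparison windows
#'
#' @param season "summer" or "winter".
#' @return list of two c(start, end) clock-minute windows.
#' @export
season_windows <- function(season) {
  season <- match.arg(season, SEASONS)
  if (season == "summer") {
    list(morning = c(parse_clock("07:00"), parse_clock("10:00")),
         evening = c(parse_clock("19:00"), parse_clock("21:30")))
  } else {
    list(morning = c(parse_clock("07:00"), parse_clock("09:00")),
         evening = c(parse_clock("20:00"), parse_clock("22:00")))
  }
}

#' Cumulative activity within a clock window, per day
#'
#' Sums raw epoch counts whose epoch start falls in `[start, end)` over the
#' whole recording and divides by the number of civil days covered, so
#' participants with different recording lengths are comparable.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param window numeric c(start, end) in clock minutes, within one day.
#' @return mean daily cumulative counts in the window.
#' @export
window_activity_totals <- function(series, window) {
  stopifnot(length(window) == 2L)
  if (window[2] <= window[1]) stop("empty or inverted window")
  mod <- epoch_minute_of_day(series)
  dates <- epoch_date(series)
  full <- names(which(table(dates) == MIN_PER_DAY))
  if (length(full) < 1L) stop("need at least one full civil day of data")
  keep <- dates %in% as.Date(full)
  inwin <- keep & mod >= window[1] & mod < window[2]
  sum(series$activity[inwin], na.rm = TRUE) / length(full)
}
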