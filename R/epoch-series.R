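#' Epoch series: one participant's uniformly sampled wearable record
#'
#' A light container for activity counts and white-light lux sampled on a
#' fixed epoch grid (60 s default, 15 s supported). Timestamps are implied by
#' `start + k * epoch_length` and are treated as local civil time with no
#' daylight-saving adjustment within a recording; internally all POSIXct
#' values use UTC so the grid is exactly uniform.
#'
#' @param participant_id character scalar.
#' @param start POSIXct (or "YYYY-MM-DD HH:MM:SS" string) of the first epoch.
#' @param epoch_length epoch duration in seconds, 15 or 60.
#' @param activity non-negative counts per epoch (NA allowed for off-wrist).
#' @param lux non-negative white-light illuminance per epoch.
#' @param off_wrist logical; off-wrist epochs carry activity/lux as missing
#'   in all downstream computation.
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, start, epoch_length, activity, lux,
                         off_wrist = rep(FALSE, length(activity))) {
  if (is.character(start)) start <- as.POSIXct(start, tz = "UTC")
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L)
  attr(start, "tzone") <- "UTC"
  epoch_length <- as.integer(epoch_length)
  if (!epoch_length %in% c(15L, 60L)) {
    stop("epoch_length must be 15 or 60 seconds, got ", epoch_length)
  }
  n <- length(activity)
  if (n < 1L || length(lux) != n || length(off_wrist) != n) {
    stop("activity, lux and off_wrist must have equal length >= 1")
  }
  activity <- as.numeric(activity)
  lux <- as.numeric(lux)
  off_wrist <- as.logical(off_wrist)
  off_wrist[is.na(off_wrist)] <- FALSE
  if (any(activity < 0, na.rm = TRUE)) stop("negative activity counts")
  if (any(lux < 0, na.rm = TRUE)) stop("negative lux values")
  # off-wrist epochs are masked for every downstream computation
  activity[off_wrist] <- NA_real_
  lux[off_wrist] <- NA_real_
  structure(
    list(participant_id = as.character(participant_id), start = start,
         epoch_length = epoch_length, activity = activity, lux = lux,
         off_wrist = off_wrist),
    class = "epoch_series"
  )
}

#' @export
length.epoch_series <- function(x) length(x$activity)

#' @method print epoch_series
#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s: %d epochs of %d s from %s (%.1f days)\n",
              x$participant_id, length(x), x$epoch_length,
              format(x$start, "%Y-%m-%d %H:%M"),
              length(x) * x$epoch_length / 86400))
  invisible(x)
}

#' Epoch timestamps implied by the grid
#' @param series an `epoch_series`.
#' @return POSIXct vector of epoch start times.
#' @export
epoch_times <- function(series) {
  series$start + (seq_len(length(series)) - 1L) * series$epoch_length
}

#' Minute-of-day for each epoch (fractional for 15-s grids)
#' @param series an `epoch_series`.
#' @export
epoch_minute_of_day <- function(series) {
  t0 <- as.numeric(series$start) %% 86400
  ((t0 + (seq_len(length(series)) - 1L) * series$epoch_length) %% 86400) / 60
}

#' Calendar date of each epoch
#' @param series an `epoch_series`.
#' @export
epoch_date <- function(series) {
  as.Date(epoch_times(series), tz = "UTC")
}

#' Aggregate an epoch series onto a coarser grid
#'
#' Activity is summed within each target window (counts are extensive), lux
#' averaged, off-wrist true if any source epoch was off wrist. A trailing
#' partial window is dropped rather than scaled.
#'
#' @param series an `epoch_series`.
#' @param target target epoch length in seconds; must be a multiple of the
#'   current epoch length.
#' @return an `epoch_series` at the target resolution.
#' @export
resample_epochs <- function(series, target) {
  target <- as.integer(target)
  if (target %% series$epoch_length != 0L) {
    stop("target (", target, " s) is not a multiple of the epoch length (",
         series$epoch_length, " s)")
  }
  k <- target %/% series$epoch_length
  if (k == 1L) return(series)
  n_out <- length(series) %/% k
  if (n_out < 1L) stop("series shorter than one target window")
  idx <- rep(seq_len(n_out), each = k)
  keep <- seq_len(n_out * k)
  act <- tapply(series$activity[keep], idx, function(v) {
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
  lx <- tapply(series$lux[keep], idx, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  ow <- tapply(series$off_wrist[keep], idx, any)
  epoch_series(series$participant_id, series$start, target,
               as.numeric(act), as.numeric(lx), as.logical(ow))
}
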