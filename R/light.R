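#' Daily 50-lux light-exposure metrics
#'
#' For each civil day: the clock time of the first and last epoch at or
#' above the lux threshold (threshold inclusive) and the total duration
#' above it (one minute per qualifying epoch, so non-contiguous exposure
#' sums correctly). Days are bounded at civil midnight — first/last exposure
#' are diurnal events. Off-wrist epochs are ignored.
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param threshold lux (default 50).
#' @return data.frame with one row per civil day: `date`, `first_time`,
#'   `last_time` (clock minutes, NA when no exposure), `duration` (min).
#' @export
daily_light_metrics <- function(series, threshold = 50) {
  if (series$epoch_length != 60L) {
    stop("light metrics require 60-s epochs; resample_epochs() first")
  }
  mod <- epoch_minute_of_day(series)
  dates <- epoch_date(series)
  hit <- !is.na(series$lux) & series$lux >= threshold
  out <- lapply(unique(dates), function(d) {
    sel <- dates == d
    h <- hit[sel]; m <- mod[sel]
    if (!any(h)) {
      data.frame(date = d, first_time = NA_real_, last_time = NA_real_,
                 duration = 0)
    } else {
      data.frame(date = d, first_time = m[which(h)[1]],
                 last_time = m[which(h)[sum(h)]],
                 duration = sum(h))
    }
  })
  do.call(rbind, out)
}

#' Per-participant light-exposure summary
#'
#' First/last exposure times are averaged circularly over days that had any
#' exposure; days with no exposure contribute a 0 to the mean duration but
#' are omitted from the timing means.
#'
#' @param days data.frame from [daily_light_metrics()].
#' @return one-row data.frame: `mean_first_time`, `mean_last_time` (clock
#'   minutes), `mean_duration` (min), `n_days`, `n_days_exposed`.
#' @export
participant_light_summary <- function(days) {
  if (nrow(days) == 0L) stop("no light days to summarise")
  exposed <- days[!is.na(days$first_time), , drop = FALSE]
  data.frame(
    mean_first_time = if (nrow(exposed)) circular_mean_clock_time(exposed$first_time) else NA_real_,
    mean_last_time = if (nrow(exposed)) circular_mean_clock_time(exposed$last_time) else NA_real_,
    mean_duration = mean(days$duration),
    n_days = nrow(days),
    n_days_exposed = nrow(exposed)
  )
}
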