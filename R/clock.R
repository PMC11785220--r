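#' Clock-time utilities
#'
#' Clock times are carried as minutes after midnight in `[0, 1440)`.
#' Sleep-timing parameters cross midnight, so nightly onset/offset are stored
#' noon-referenced (minutes after the preceding 12:00); these helpers convert
#' between the two representations and do circular (mod 24 h) arithmetic.
#'
#' @name clock
NULL

MIN_PER_DAY <- 1440L

#' Parse "HH:MM" (or "HH:MM:SS") clock strings to minutes after midnight
#'
#' @param x character vector; empty strings and NA parse to NA.
#' @return numeric vector of minutes in `[0, 1440)`.
#' @export
parse_clock <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(trimws(x))
  if (any(ok)) {
    parts <- strsplit(trimws(x[ok]), ":", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) < 2L || anyNA(suppressWarnings(as.numeric(p))), logical(1))
    if (any(bad)) {
      stop("unparseable clock time(s): ", paste(unique(x[ok][bad]), collapse = ", "))
    }
    out[ok] <- vapply(parts, function(p) {
      v <- as.numeric(p)
      v[1] * 60 + v[2] + if (length(v) >= 3) v[3] / 60 else 0
    }, numeric(1))
    if (any(out[ok] < 0 | out[ok] >= MIN_PER_DAY)) {
      stop("clock time out of range [00:00, 24:00)")
    }
  }
  out
}

#' Format minutes after midnight as "HH:MM"
#'
#' Values are wrapped mod 24 h and rounded to the nearest minute.
#' @param m numeric minutes.
#' @export
format_clock <- function(m) {
  out <- rep(NA_character_, length(m))
  ok <- !is.na(m)
  mm <- round(m[ok]) %% MIN_PER_DAY
  out[ok] <- sprintf("%02d:%02d", mm %/% 60, mm %% 60)
  out
}

#' Signed circular difference between two clock times, in minutes
#'
#' Returns a - b wrapped to (-720, 720], so 23:50 vs 00:10 is -20 min,
#' not +1420.
#' @param a,b minutes after midnight.
#' @export
clock_diff_minutes <- function(a, b) {
  d <- (a - b) %% MIN_PER_DAY
  ifelse(d > MIN_PER_DAY / 2, d - MIN_PER_DAY, d)
}

#' Convert clock time to noon-referenced minutes
#'
#' Minutes after the preceding 12:00, so evening times (18:00 = 360) sort
#' before post-midnight times (01:00 = 780) and a night is a contiguous
#' interval.
#' @param m minutes after midnight.
#' @export
noon_minutes <- function(m) (m - MIN_PER_DAY / 2) %% MIN_PER_DAY

#' Convert noon-referenced minutes back to clock minutes after midnight
#' @param m noon-referenced minutes.
#' @export
noon_to_clock <- function(m) (m + MIN_PER_DAY / 2) %% MIN_PER_DAY

#' Circular mean of clock times
#'
#' Each time maps to a unit vector at angle 2*pi*minutes/1440; the mean
#' direction is returned as a clock time. Errors when the resultant length is
#' numerically zero (antipodal/degenerate configurations have no mean
#' direction).
#'
#' @param times numeric vector, minutes after midnight; NAs dropped.
#' @return mean clock time in minutes `[0, 1440)`.
#' @export
circular_mean_clock_time <- function(times) {
  times <- times[!is.na(times)]
  if (length(times) == 0L) stop("circular mean of an empty set of times")
  th <- 2 * pi * times / MIN_PER_DAY
  s <- sum(sin(th)); c <- sum(cos(th))
  if (sqrt(s^2 + c^2) / length(times) < 1e-9) {
    stop("degenerate circular mean: resultant length is zero")
  }
  out <- (atan2(s, c) / (2 * pi) * MIN_PER_DAY) %% MIN_PER_DAY
  if (out > MIN_PER_DAY - 1e-6) out <- 0  # floating wrap at exactly 24:00
  out
}

#' Circular standard deviation of clock times, in minutes
#'
#' The directional-statistics estimator sqrt(-2 log R) mapped from radians to
#' minutes (R = mean resultant length). Zero when all times coincide.
#' @param times minutes after midnight; NAs dropped.
#' @export
circular_sd_clock_time <- function(times) {
  times <- times[!is.na(times)]
  if (length(times) == 0L) stop("circular SD of an empty set of times")
  th <- 2 * pi * times / MIN_PER_DAY
  r <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  r <- min(r, 1)
  sqrt(-2 * log(r)) * MIN_PER_DAY / (2 * pi)
}

#' Midsleep clock time of a night
#'
#' @param onset clock minutes after midnight.
#' @param duration minutes, strictly inside (0, 1440).
#' @return clock minutes of (onset + duration/2) mod 24 h.
#' @export
night_midsleep <- function(onset, duration) {
  if (any(!is.na(duration) & (duration <= 0 | duration >= MIN_PER_DAY))) {
    stop("duration must lie strictly between 0 and 24 h")
  }
  (onset + duration / 2) %% MIN_PER_DAY
}
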