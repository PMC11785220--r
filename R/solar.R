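#' Daylight geometry and an outdoor illuminance profile
#'
#' Standard solar-declination geometry: declination
#' delta = -23.44 deg * cos(2 pi (N + 10) / 365) for day-of-year N, sunrise
#' hour angle omega0 = acos(-tan(phi) tan(delta)). Outdoor illuminance is
#' modelled as proportional to the sine of solar elevation (clear-sky scale
#' 120,000 lux at the zenith), which is zero before sunrise and after sunset
#' and smooth through the midday maximum. Solar noon is taken at 12:00 local
#' time; no refraction or twilight model.
#'
#' @name solar
NULL

solar_declination <- function(date) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
}

#' Daylength in hours on a date at a latitude
#' @param date Date or string.
#' @param latitude degrees, |latitude| < 66.5.
#' @export
daylength_hours <- function(date, latitude) {
  if (abs(latitude) >= 66.5) stop("polar latitudes unsupported (|lat| >= 66.5)")
  delta <- solar_declination(date)
  phi <- latitude * pi / 180
  2 * acos(pmin(1, pmax(-1, -tan(phi) * tan(delta)))) * 12 / pi
}

#' Outdoor daylight illuminance over 24 h
#'
#' @param date Date (or string) of the civil day.
#' @param latitude degrees; polar latitudes rejected.
#' @param epoch_length seconds per epoch (60 default).
#' @param peak_lux clear-sky zenith illuminance scale (lux).
#' @return numeric vector of lux, one value per epoch starting 00:00.
#' @export
solar_daylight_profile <- function(date, latitude, epoch_length = 60,
                                   peak_lux = 120000) {
  if (abs(latitude) >= 66.5) stop("polar latitudes unsupported (|lat| >= 66.5)")
  delta <- solar_declination(date)
  phi <- latitude * pi / 180
  n <- 86400 %/% epoch_length
  # hour angle: 0 at solar noon (12:00 local), 15 deg per hour
  hours <- (seq_len(n) - 1L) * epoch_length / 3600
  ha <- (hours - 12) * pi / 12
  sin_elev <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(ha)
  peak_lux * pmax(0, sin_elev)
}
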