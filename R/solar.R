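#' Solar declination (radians)
#'
#' Standard sinusoidal approximation of the Sun's declination as a function of
#' day of year.
#' @param doy day of year (1..366).
#' @return declination in radians.
#' @keywords internal
solar_declination <- function(doy) {
  (23.44 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
}

#' Photoperiod (day length) from latitude and day of year
#'
#' Geometric sunrise/sunset hour-angle formula (sun centre on the horizon,
#' no refraction), the photoperiod convention of VGPM-family production
#' codes. Polar day and polar night are clamped to 24 h and 0 h.
#'
#' @param lat latitude, degrees (-90..90).
#' @param doy day of year (1..366). Vectorised over both arguments.
#' @return day length in hours, in \[0, 24\].
#' @examples
#' day_length(0, 80)     # ~12 h at the equator
#' day_length(-70, 355)  # austral polar day -> 24 h
#' @export
day_length <- function(lat, doy) {
  stopifnot(all(lat >= -90 & lat <= 90), all(doy >= 1 & doy <= 366))
  decl <- solar_declination(doy)
  cos_h <- -tan(lat * pi / 180) * tan(decl)
  ifelse(cos_h >= 1, 0, ifelse(cos_h <= -1, 24, 2 * acos(cos_h) * 180 / pi / 15))
}

#' Is the sun above the horizon?
#'
#' Used to classify float profiles as day or night from their time and
#' position.
#' @param lat,lon degrees.
#' @param doy day of year.
#' @param hour_utc decimal UTC hour.
#' @return logical.
#' @export
is_daylight <- function(lat, lon, doy, hour_utc) {
  decl <- solar_declination(doy)
  # local solar hour angle, degrees
  h <- (hour_utc + lon / 15 - 12) * 15 * pi / 180
  latr <- lat * pi / 180
  sin_elev <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(h)
  sin_elev > 0
}
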