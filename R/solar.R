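#' Solar position (zenith and azimuth)
#'
#' NOAA/Meeus low-precision solar ephemeris: apparent solar longitude,
#' declination and the equation of time drive the local hour angle; accuracy
#' is a few hundredths of a degree over 1950-2050, well inside the 0.5 degree
#' contract. Azimuth is measured clockwise from north; zenith is the angle
#' from the local vertical, without atmospheric refraction.
#'
#' @param latitude degrees north.
#' @param longitude degrees east.
#' @param date calendar date, `"YYYY-MM-DD"` or a `Date`.
#' @param hour local clock time as decimal hours (e.g. 12.5 = 12:30).
#' @param utc_offset hours east of UTC for the local clock (no DST applied).
#' @return list of class `solar_geometry`: `zenith`, `azimuth` (degrees),
#'   `declination`, `eq_time_min`, `daylight` (TRUE when zenith < 90),
#'   plus the call inputs.
#' @examples
#' sun_position(40.154, 116.133, "2021-08-31", 12, utc_offset = 8)
#' @export
sun_position <- function(latitude, longitude, date, hour, utc_offset = 0) {
  if (abs(latitude) > 90 || abs(longitude) > 180)
    stop("sun_position: invalid coordinates")
  if (!is.finite(hour) || hour < 0 || hour >= 24)
    stop("sun_position: hour must be in [0, 24)")
  d <- as.Date(date)
  rad <- pi / 180
  jd <- as.numeric(d) + 2440587.5 + (hour - utc_offset) / 24
  jc <- (jd - 2451545) / 36525

  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqc <- sin(gma * rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gma * rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gma * rad) * 0.000289
  stl <- gml + eqc
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * rad)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc  <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * rad)
  decl <- asin(sin(oc * rad) * sin(sal * rad)) / rad
  vy <- tan(oc / 2 * rad)^2
  eqt <- 4 / rad * (vy * sin(2 * gml * rad) - 2 * ecc * sin(gma * rad) +
    4 * ecc * vy * sin(gma * rad) * cos(2 * gml * rad) -
    0.5 * vy^2 * sin(4 * gml * rad) - 1.25 * ecc^2 * sin(2 * gma * rad))

  tst <- (hour * 60 + eqt + 4 * longitude - 60 * utc_offset) %% 1440
  ha <- if (tst / 4 < 0) tst / 4 + 180 else tst / 4 - 180
  cz <- sin(latitude * rad) * sin(decl * rad) +
    cos(latitude * rad) * cos(decl * rad) * cos(ha * rad)
  cz <- pmin(pmax(cz, -1), 1)
  zen <- acos(cz) / rad
  if (zen < 1e-9) {
    az <- 180
  } else {
    ac <- (sin(latitude * rad) * cz - sin(decl * rad)) /
      (cos(latitude * rad) * sin(zen * rad))
    ac <- pmin(pmax(ac, -1), 1)
    az <- if (ha > 0) (acos(ac) / rad + 180) %% 360 else (540 - acos(ac) / rad) %% 360
  }
  structure(list(zenith = zen, azimuth = az, declination = decl,
                 eq_time_min = eqt, daylight = zen < 90,
                 latitude = latitude, longitude = longitude,
                 date = as.character(d), hour = hour, utc_offset = utc_offset),
            class = "solar_geometry")
}

#' @export
print.solar_geometry <- function(x, ...) {
  cat(sprintf("<solar_geometry> %s %05.2fh UTC%+g: zenith %.2f deg, azimuth %.2f deg%s\n",
              x$date, x$hour, x$utc_offset, x$zenith, x$azimuth,
              if (x$daylight) "" else " (night)"))
  invisible(x)
}

#' Unit vector pointing toward the sun
#'
#' @param sun a `solar_geometry` object.
#' @return numeric length-3 vector (x = east, y = north, z = up).
#' @keywords internal
sun_vector <- function(sun) {
  rad <- pi / 180
  sz <- sin(sun$zenith * rad)
  c(x = sz * sin(sun$azimuth * rad),
    y = sz * cos(sun$azimuth * rad),
    z = cos(sun$zenith * rad))
}
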