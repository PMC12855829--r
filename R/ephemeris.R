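# Low-precision analytic solar/lunar ephemeris (Astronomical Almanac / Meeus
# truncated series). Target accuracy: ~0.5 deg altitude, ~1% illuminated
# fraction -- ample for illuminance modelling and twilight classification.

.deg2rad <- pi / 180

.asUtc <- function(time) {
  if (inherits(time, "POSIXct")) return(time)
  out <- tryCatch(as.POSIXct(time, tz = "UTC"), error = function(e) NA)
  if (any(is.na(out))) stop("invalid timestamp: ", paste(time, collapse = ", "))
  out
}

# Julian day from POSIXct (UTC).
.julianDay <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

.checkEphemerisWindow <- function(time) {
  yr <- as.integer(format(time, "%Y", tz = "UTC"))
  if (any(yr < 1900 | yr > 2100)) {
    stop("ephemeris is only valid for dates between 1900 and 2100")
  }
}

# Greenwich mean sidereal time, degrees.
.gmstDeg <- function(jd) {
  (280.46061837 + 360.98564736629 * (jd - 2451545.0)) %% 360
}

# Geocentric solar ecliptic longitude (deg) and distance (AU), Almanac
# low-accuracy series.
.sunEcliptic <- function(jd) {
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * .deg2rad
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360
  R <- 1.00014 - 0.01671 * cos(g) - 0.00014 * cos(2 * g)
  list(lambda = lambda, R = R)
}

.obliquityDeg <- function(jd) {
  23.439 - 0.0000004 * (jd - 2451545.0)
}

# Equatorial coordinates (RA, Dec in degrees) from ecliptic lon/lat.
.eclToEqu <- function(lambdaDeg, betaDeg, epsDeg) {
  lam <- lambdaDeg * .deg2rad
  bet <- betaDeg * .deg2rad
  eps <- epsDeg * .deg2rad
  ra <- atan2(sin(lam) * cos(eps) - tan(bet) * sin(eps), cos(lam)) / .deg2rad
  dec <- asin(sin(bet) * cos(eps) + cos(bet) * sin(eps) * sin(lam)) / .deg2rad
  list(ra = ra %% 360, dec = dec)
}

# Altitude (deg) of a body at (ra, dec) for an observer at (lat, lon).
.altitudeDeg <- function(jd, raDeg, decDeg, lat, lon) {
  H <- (.gmstDeg(jd) + lon - raDeg) * .deg2rad
  phi <- lat * .deg2rad
  dec <- decDeg * .deg2rad
  sinh <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)
  asin(pmin(1, pmax(-1, sinh))) / .deg2rad
}

#' Geometric solar altitude
#'
#' Altitude of the Sun's centre above the horizon, without atmospheric
#' refraction, from a low-precision analytic solar position (accurate to well
#' under half a degree across 1900--2100).
#'
#' @param time a POSIXct instant (UTC) or anything coercible to one;
#'   vectorized.
#' @param lat,lon observer latitude/longitude in degrees (north/east
#'   positive).
#' @return solar altitude in degrees, in [-90, 90].
#' @examples
#' solarAltitude(as.POSIXct("2022-09-13 12:00:00", tz = "UTC"), 53.15, 13.03)
#' @export
solarAltitude <- function(time, lat, lon) {
  time <- .asUtc(time)
  .checkEphemerisWindow(time)
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90")
  jd <- .julianDay(time)
  sun <- .sunEcliptic(jd)
  equ <- .eclToEqu(sun$lambda, 0, .obliquityDeg(jd))
  .altitudeDeg(jd, equ$ra, equ$dec, lat, lon)
}

#' Classify the twilight phase from solar altitude
#'
#' Standard twilight bands: day (sun at or above the horizon), civil twilight
#' (sun 0--6 degrees below), nautical (6--12 below), astronomical (12--18
#' below), night (more than 18 below). Each boundary at an exact negative
#' altitude belongs to the darker phase, so the bands are half-open and
#' partition [-90, 90].
#'
#' @param altitudeDeg solar altitude in degrees; vectorized.
#' @return factor with levels day, civil, nautical, astronomical, night.
#' @examples
#' classifyTwilight(c(5, -4, -10, -15, -30))
#' @export
classifyTwilight <- function(altitudeDeg) {
  if (any(altitudeDeg < -90 | altitudeDeg > 90)) {
    stop("solar altitude must lie in [-90, 90]")
  }
  phase <- cut(altitudeDeg,
               breaks = c(-90.001, -18, -12, -6, 0, 90.001),
               labels = c("night", "astronomical", "nautical", "civil", "day"),
               right = FALSE)
  # exact 0 belongs to day; cut(right = FALSE) already puts 0 in [0, 90)
  factor(phase, levels = c("day", "civil", "nautical", "astronomical", "night"))
}

# Lunar ecliptic position from the truncated Meeus series: longitude to
# ~0.3 deg, latitude ~0.2 deg, distance ~500 km.
.moonEcliptic <- function(jd) {
  t <- (jd - 2451545.0) / 36525
  Lp <- (218.3164477 + 481267.88123421 * t) %% 360   # mean longitude
  D <- ((297.8501921 + 445267.1114034 * t) %% 360) * .deg2rad   # elongation
  M <- ((357.5291092 + 35999.0502909 * t) %% 360) * .deg2rad    # sun anomaly
  Mp <- ((134.9633964 + 477198.8675055 * t) %% 360) * .deg2rad  # moon anomaly
  F <- ((93.2720950 + 483202.0175233 * t) %% 360) * .deg2rad    # arg latitude
  lambda <- Lp +
    6.289 * sin(Mp) +
    1.274 * sin(2 * D - Mp) +
    0.658 * sin(2 * D) +
    0.214 * sin(2 * Mp) -
    0.186 * sin(M) -
    0.059 * sin(2 * D - 2 * Mp) -
    0.057 * sin(2 * D - M - Mp) +
    0.053 * sin(2 * D + Mp) +
    0.046 * sin(2 * D - M) +
    0.041 * sin(Mp - M) -
    0.035 * sin(D) -
    0.031 * sin(Mp + M)
  beta <- 5.128 * sin(F) +
    0.281 * sin(Mp + F) +
    0.278 * sin(Mp - F) +
    0.173 * sin(2 * D - F) +
    0.055 * sin(2 * D - Mp + F) +
    0.046 * sin(2 * D - Mp - F) +
    0.033 * sin(2 * D + F)
  dist <- 385000.56 -
    20905.355 * cos(Mp) -
    3699.111 * cos(2 * D - Mp) -
    2955.968 * cos(2 * D) -
    569.925 * cos(2 * Mp)
  list(lambda = lambda %% 360, beta = beta, dist = dist)
}

#' Lunar geometry and disc illumination at an instant
#'
#' Computes the Moon's geometric altitude, the Sun--Moon phase angle, the
#' illuminated fraction of the lunar disc `(1 + cos(phase)) / 2`, and the
#' Earth--Moon distance, from a truncated analytic lunar theory. This replaces
#' a table lookup of lunar phase and altitude with a deterministic in-package
#' ephemeris (about 1% accuracy on the illuminated fraction).
#'
#' @inheritParams solarAltitude
#' @param cloudOkta observed cloud cover in oktas (0--8), carried through to
#'   the illuminance model; default 0 (clear sky).
#' @return a [SkyState-class] object.
#' @examples
#' lunarState(as.POSIXct("2022-09-13 00:00:00", tz = "UTC"), 53.15, 13.03)
#' @export
lunarState <- function(time, lat, lon, cloudOkta = 0L) {
  time <- .asUtc(time)
  .checkEphemerisWindow(time)
  if (length(time) != 1L) stop("lunarState expects a single instant")
  jd <- .julianDay(time)
  eps <- .obliquityDeg(jd)

  moon <- .moonEcliptic(jd)
  sun <- .sunEcliptic(jd)

  mequ <- .eclToEqu(moon$lambda, moon$beta, eps)
  lunarAlt <- .altitudeDeg(jd, mequ$ra, mequ$dec, lat, lon)

  # geocentric elongation, then phase angle from the plane triangle
  # Sun--Earth--Moon
  psi <- acos(pmin(1, pmax(-1,
    cos(moon$beta * .deg2rad) * cos((moon$lambda - sun$lambda) * .deg2rad))))
  sunKm <- sun$R * 149597870.7
  phase <- atan2(sunKm * sin(psi), moon$dist - sunKm * cos(psi)) / .deg2rad
  frac <- (1 + cos(phase * .deg2rad)) / 2

  new("SkyState",
      time = time, lat = lat, lon = lon,
      solarAltitude = solarAltitude(time, lat, lon),
      lunarAltitude = lunarAlt,
      lunarPhaseAngle = phase,
      illuminatedFraction = frac,
      lunarDistance = moon$dist,
      cloudOkta = as.integer(cloudOkta))
}

# Evening sunset instant (geometric solar altitude crossing 0 downward) for
# the civil date holding `date`'s local evening; search window in UTC.
.sunsetUtc <- function(date, lat, lon) {
  day0 <- as.POSIXct(paste(format(date, "%Y-%m-%d"), "00:00:00"), tz = "UTC")
  grid <- day0 + 3600 * seq(6, 30, by = 0.5)
  alt <- solarAltitude(grid, lat, lon)
  drop <- which(alt[-length(alt)] >= 0 & alt[-1] < 0)
  if (!length(drop)) stop("no sunset found in the search window")
  i <- drop[1]
  f <- stats::uniroot(function(h) solarAltitude(day0 + h * 3600, lat, lon),
                      interval = c(6 + (i - 1) * 0.5, 6 + i * 0.5),
                      tol = 1e-6)
  day0 + f$root * 3600
}
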