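# Simplified night-sky illuminance model: a piecewise solar daylight/twilight
# curve, a lunar brightness law with phase-angle dependence, airmass
# extinction and inverse-square distance, a fixed starlight baseline, and a
# multiplicative cloud transmission factor per okta.

#' Parameters of the surface illuminance model
#'
#' @param extinctionMagPerAirmass atmospheric extinction, magnitudes per
#'   airmass (default 0.25, a clear continental atmosphere).
#' @param starlightLux moonless clear-sky baseline illuminance (default
#'   0.001 lx, typical starlight plus airglow).
#' @param oktaTransmission length-9 vector of transmission factors for okta
#'   0..8; must be non-increasing.
#' @return named list of validated parameters.
#' @export
lightParams <- function(extinctionMagPerAirmass = 0.25,
                        starlightLux = 0.001,
                        oktaTransmission = c(1.00, 0.96, 0.91, 0.85, 0.78,
                                             0.69, 0.59, 0.46, 0.30)) {
  if (length(oktaTransmission) != 9L || any(diff(oktaTransmission) > 0)) {
    stop("oktaTransmission must be 9 non-increasing factors for okta 0..8")
  }
  list(extinctionMagPerAirmass = extinctionMagPerAirmass,
       starlightLux = starlightLux,
       oktaTransmission = oktaTransmission)
}

# Solar horizontal illuminance (lux) vs geometric altitude: piecewise linear
# in log10(lux) through the twilight bands, joined continuously to a sine law
# above the horizon. Zero below -18 deg (starlight is added separately).
.solarLux <- function(altDeg) {
  out <- numeric(length(altDeg))
  kx <- c(-18, -12, -6, 0)
  ky <- c(-3.1, -2.1, 0.48, log10(750))
  tw <- altDeg >= -18 & altDeg < 0
  out[tw] <- 10^stats::approx(kx, ky, xout = altDeg[tw])$y
  up <- altDeg >= 0
  out[up] <- 750 + 118000 * sin(altDeg[up] * pi / 180)
  out
}

# Rozenberg airmass, valid down to the horizon.
.airmass <- function(altDeg) {
  s <- sin(pmax(altDeg, 0) * pi / 180)
  1 / (s + 0.025 * exp(-11 * s))
}

# Lunar horizontal illuminance (lux): phase-angle magnitude law, inverse
# square distance, airmass extinction, sin(altitude) projection.
.lunarLux <- function(altDeg, phaseDeg, distKm, kExt) {
  if (altDeg <= 0) return(0)
  m <- -12.73 + 0.026 * abs(phaseDeg) + 4e-9 * phaseDeg^4
  eZen <- 10^((-14.18 - m) / 2.5)
  eZen * sin(altDeg * pi / 180) *
    10^(-0.4 * kExt * .airmass(altDeg)) *
    (385000.56 / distKm)^2
}

#' Model total downwelling surface illuminance
#'
#' Sums a solar daylight/twilight term (a function of solar altitude), a
#' lunar term (phase-angle brightness law, airmass extinction, inverse-square
#' Earth--Moon distance, horizontal projection) and a fixed starlight
#' baseline, then applies a multiplicative cloud transmission factor for the
#' recorded okta. The moon contributes nothing below the horizon.
#'
#' @param sky a [SkyState-class], e.g. from [lunarState()].
#' @param params model parameters from [lightParams()].
#' @return illuminance in lux (non-negative scalar).
#' @examples
#' sky <- lunarState(as.POSIXct("2022-09-13 22:00:00", tz = "UTC"),
#'                   53.15, 13.03)
#' surfaceIlluminance(sky)
#' @export
surfaceIlluminance <- function(sky, params = lightParams()) {
  stopifnot(is(sky, "SkyState"))
  if (is.null(params$extinctionMagPerAirmass)) {
    stop("light model params are missing 'extinctionMagPerAirmass'")
  }
  if (is.null(params$starlightLux) || is.null(params$oktaTransmission)) {
    stop("light model params are incomplete; use lightParams()")
  }
  e <- .solarLux(sky@solarAltitude) +
    .lunarLux(sky@lunarAltitude, sky@lunarPhaseAngle, sky@lunarDistance,
              params$extinctionMagPerAirmass) +
    params$starlightLux
  e * params$oktaTransmission[sky@cloudOkta + 1L]
}

#' Attenuate surface illuminance into depth bins
#'
#' Beer--Lambert decay `E(z) = E0 * exp(-Kd * z)` evaluated at the midpoints
#' of half-open depth bins `[z, z + h)`; values below the scotopic floor
#' (default 0.001 lx, the lowest visual sensitivity reported for fish) are
#' set to exactly zero.
#'
#' @param surfaceLux illuminance just below the surface, lux, >= 0.
#' @param kdPerM diffuse attenuation coefficient, 1/m, >= 0.
#' @param binEdges increasing bin edges in metres; default 10 cm bins to
#'   16.7 m (167 bins).
#' @param floorLux detection floor in lux (default 0.001).
#' @param wavelengthNm nominal wavelength recorded for radiometric
#'   conversions (default 500 nm).
#' @return a [LightProfile-class].
#' @examples
#' lp <- attenuateProfile(0.06, kdPerM = 0.25)
#' head(illuminance(lp))
#' @export
attenuateProfile <- function(surfaceLux, kdPerM,
                             binEdges = seq(0, 16.7, by = 0.1),
                             floorLux = 0.001, wavelengthNm = 500) {
  if (surfaceLux < 0) stop("surfaceLux must be non-negative")
  if (kdPerM < 0) stop("kdPerM must be non-negative")
  mids <- (binEdges[-1] + binEdges[-length(binEdges)]) / 2
  e <- surfaceLux * exp(-kdPerM * mids)
  e[e < floorLux] <- 0
  new("LightProfile", binEdges = binEdges, illuminance = e,
      surfaceLux = surfaceLux, kd = kdPerM, wavelength = wavelengthNm,
      floorLux = floorLux)
}

#' Per-bin illuminance of a light profile
#' @param x a [LightProfile-class].
#' @return numeric vector of per-bin illuminance, lux.
#' @export
illuminance <- function(x) {
  stopifnot(is(x, "LightProfile"))
  x@illuminance
}

#' Bin midpoint depths of a light profile
#' @param x a [LightProfile-class].
#' @return numeric vector of bin midpoint depths, metres.
#' @export
binMidDepth <- function(x) {
  stopifnot(is(x, "LightProfile"))
  (x@binEdges[-1] + x@binEdges[-length(x@binEdges)]) / 2
}

#' Tabulate a light profile with radiometric conversions
#'
#' One row per 10 cm bin with illuminance and its monochromatic irradiance
#' and photon-flux equivalents at the profile's nominal wavelength.
#'
#' @param x a [LightProfile-class].
#' @param profileId identifier written into the first column.
#' @return data.frame with columns profile_id, bin_index, bin_mid_depth_m,
#'   illuminance_lx, irradiance_w_m2, photon_flux_umol.
#' @export
lightProfileTable <- function(x, profileId = "profile") {
  stopifnot(is(x, "LightProfile"))
  w <- luxToIrradiance(x@illuminance, x@wavelength)
  data.frame(
    profile_id = profileId,
    bin_index = seq_along(x@illuminance) - 1L,
    bin_mid_depth_m = binMidDepth(x),
    illuminance_lx = x@illuminance,
    irradiance_w_m2 = w,
    photon_flux_umol = irradianceToPhotonFlux(w, x@wavelength))
}
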