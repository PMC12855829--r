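# Radiometric conversions between photometric (lux) and radiometric /
# quantum units at a nominal monochromatic wavelength.

# CIE 1931 2-degree photopic luminosity function V(lambda), 380-780 nm at
# 5 nm steps.
.cieWavelength <- seq(380, 780, by = 5)
.cieV <- c(
  0.000039, 0.000064, 0.000120, 0.000217, 0.000396, 0.000640, 0.001210,
  0.002180, 0.004000, 0.007300, 0.011600, 0.016840, 0.023000, 0.029800,
  0.038000, 0.048000, 0.060000, 0.073900, 0.090980, 0.112600, 0.139020,
  0.169300, 0.208020, 0.258600, 0.323000, 0.407300, 0.503000, 0.608200,
  0.710000, 0.793200, 0.862000, 0.914850, 0.954000, 0.980300, 0.994950,
  1.000000, 0.995000, 0.978600, 0.952000, 0.915400, 0.870000, 0.816300,
  0.757000, 0.694900, 0.631000, 0.566800, 0.503000, 0.441200, 0.381000,
  0.321000, 0.265000, 0.217000, 0.175000, 0.138200, 0.107000, 0.081600,
  0.061000, 0.044580, 0.032000, 0.023200, 0.017000, 0.011920, 0.008210,
  0.005723, 0.004102, 0.002929, 0.002091, 0.001484, 0.001047, 0.000740,
  0.000520, 0.000361, 0.000249, 0.000172, 0.000120, 0.000085, 0.000060,
  0.000042, 0.000030, 0.000021, 0.000015)

#' Photopic luminosity function V(lambda)
#'
#' Linear interpolation of the CIE 1931 2-degree photopic luminosity table
#' (380--780 nm at 5 nm steps).
#'
#' @param wavelengthNm wavelength in nanometres; vectorized.
#' @return unitless sensitivity in (0, 1].
#' @examples
#' photopicSensitivity(c(500, 520, 555))
#' @export
photopicSensitivity <- function(wavelengthNm) {
  if (any(wavelengthNm < 380 | wavelengthNm > 780)) {
    stop("wavelength must lie within the 380-780 nm photopic table")
  }
  stats::approx(.cieWavelength, .cieV, xout = wavelengthNm)$y
}

#' Convert illuminance to monochromatic irradiance
#'
#' Under a monochromatic approximation at wavelength lambda, illuminance E_v
#' (lux) corresponds to irradiance `E_e = E_v / (683 * V(lambda))` in W m^-2,
#' with V the photopic luminosity function. Used to express underwater light
#' levels near the scotopic floor in radiometric units.
#'
#' @param lux illuminance in lux, >= 0; vectorized.
#' @param wavelengthNm nominal wavelength in nm (blue-green underwater
#'   spectra are approximated at 480--520 nm).
#' @return irradiance in W m^-2.
#' @examples
#' luxToIrradiance(0.06, 500)   # ~2.72e-4 W m^-2
#' @export
luxToIrradiance <- function(lux, wavelengthNm) {
  if (any(lux < 0)) stop("lux must be non-negative")
  lux / (683 * photopicSensitivity(wavelengthNm))
}

#' Convert monochromatic irradiance back to illuminance
#'
#' Inverse of [luxToIrradiance()] at the same wavelength.
#'
#' @param wM2 irradiance in W m^-2, >= 0.
#' @inheritParams luxToIrradiance
#' @return illuminance in lux.
#' @export
irradianceToLux <- function(wM2, wavelengthNm) {
  if (any(wM2 < 0)) stop("irradiance must be non-negative")
  wM2 * 683 * photopicSensitivity(wavelengthNm)
}

#' Convert irradiance to photon flux
#'
#' For monochromatic light of wavelength lambda, photon flux is
#' `W * lambda / (h c N_A)`, i.e. `W * lambda[nm] * 8.3594e-3` umol photons
#' m^-2 s^-1 per W m^-2.
#'
#' @inheritParams irradianceToLux
#' @return photon flux in umol m^-2 s^-1.
#' @examples
#' irradianceToPhotonFlux(2.72e-4, 500)   # ~1.14e-3 umol m^-2 s^-1
#' @export
irradianceToPhotonFlux <- function(wM2, wavelengthNm) {
  if (any(wM2 < 0)) stop("irradiance must be non-negative")
  if (any(wavelengthNm <= 0)) stop("wavelength must be positive")
  h <- 6.62607015e-34; c <- 2.99792458e8; nA <- 6.02214076e23
  wM2 * (wavelengthNm * 1e-9) / (h * c * nA) * 1e6
}
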