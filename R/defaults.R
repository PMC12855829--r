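# Default effect sizes, size-class definitions and instrument optics for the
# Lake Stechlin diel-vertical-migration study system. The coefficient vectors
# are the package's generating truth for simulation and recovery testing.

.nightTerms <- c(
  "(Intercept)", "size_medium", "size_large", "lx", "temp", "chl",
  "lx:size_medium", "lx:size_large", "temp:size_medium", "temp:size_large",
  "lx:temp", "chl:size_medium", "chl:size_large", "lx:chl",
  "lx:temp:size_medium", "lx:temp:size_large",
  "lx:chl:size_medium", "lx:chl:size_large")

.dayNightTerms <- c(
  "(Intercept)", "lx", "size_medium", "size_large",
  "lx:size_medium", "lx:size_large")

#' Default night-design fixed effects
#'
#' Generating coefficients (log-mean scale, standardized covariates) for the
#' night model of depth-bin density: illuminance x size class x temperature
#' and illuminance x size class x chlorophyll-a, with small as the reference
#' size class. Values are the estimated effect sizes for cladocerans and
#' copepods in the Lake Stechlin study system and serve as simulation truth
#' for parameter-recovery tests.
#'
#' @param taxon "cladoceran" or "copepod".
#' @return named numeric vector of 18 coefficients.
#' @export
nightEffectDefaults <- function(taxon = c("cladoceran", "copepod")) {
  taxon <- match.arg(taxon)
  vals <- switch(taxon,
    cladoceran = c(1.58, -0.03, -0.09, -0.03, 0.10, 0.10,
                   -0.01, 0.05, 0.19, 0.43, 0.12, -0.04, -0.08, -0.03,
                   -0.08, -0.24, 0.01, 0.07),
    copepod = c(1.71, -0.01, -0.01, -0.02, -0.04, 0.17,
                0.00, 0.05, -0.03, 0.17, 0.11, 0.06, 0.12, -0.02,
                -0.09, -0.15, -0.07, -0.03))
  stats::setNames(vals, .nightTerms)
}

#' Default day--night design fixed effects
#'
#' Generating coefficients for the day-to-night model: raw illuminance (lux)
#' interacting with size class. Illuminance spans roughly five orders of
#' magnitude from daylight to night, hence the per-lux slopes of order 1e-6.
#'
#' @inheritParams nightEffectDefaults
#' @return named numeric vector of 6 coefficients.
#' @export
dayNightEffectDefaults <- function(taxon = c("cladoceran", "copepod")) {
  taxon <- match.arg(taxon)
  vals <- switch(taxon,
    cladoceran = c(1.55, -3.98e-6, -3.31e-3, -3.74e-3, -1.80e-6, -5.52e-6),
    copepod = c(1.75, -7.42e-6, -3.90e-3, -1.70e-3, -4.50e-6, -8.61e-6))
  stats::setNames(vals, .dayNightTerms)
}

#' Size-class ESD ranges
#'
#' Closed equivalent-spherical-diameter intervals (mm) defining the small,
#' medium and large size classes per taxon, taken from the modes of the
#' measured size histograms of the study system. Values between ranges are
#' unclassified.
#'
#' @inheritParams nightEffectDefaults
#' @return 3x2 matrix (rows small/medium/large; columns lo/hi), mm.
#' @export
sizeClassRanges <- function(taxon = c("cladoceran", "copepod")) {
  taxon <- match.arg(taxon)
  m <- switch(taxon,
    cladoceran = rbind(small = c(0.36, 0.39), medium = c(0.45, 0.53),
                       large = c(0.70, 0.75)),
    copepod = rbind(small = c(0.36, 0.37), medium = c(0.45, 0.47),
                    large = c(0.66, 0.68)))
  colnames(m) <- c("lo", "hi")
  m
}

#' Shadowgraph imager optics
#'
#' Geometry and acquisition constants of the shadowgraph plankton imager:
#' a 43 mm (height) x 52 mm (breadth) image field across a 100 mm water
#' path, 21 um pixel pitch, 2.4 frames per second at a 5 m/min descent.
#' `scaleFactor` in {1, 2, 4, 8} downsamples the frame grid (pixel pitch
#' multiplied, pixel counts divided) for desk-scale runs.
#'
#' @param scaleFactor integer downscaling factor for rendered frames.
#' @return named list of optics constants, including the derived descent per
#'   frame (mm) and fully-covered 10 cm bin volume (litres).
#' @examples
#' opticsConfig()$descentPerFrameMm   # 34.72 mm -> 8.28 mm frame overlap
#' @export
opticsConfig <- function(scaleFactor = 1L) {
  if (!scaleFactor %in% c(1L, 2L, 4L, 8L)) {
    stop("scaleFactor must be one of 1, 2, 4, 8")
  }
  pitch <- 0.021 * scaleFactor
  height <- 43; breadth <- 52; path <- 100
  rate <- 2.4; descent <- 5  # m/min
  list(
    frameHeightMm = height,
    frameBreadthMm = breadth,
    pathLengthMm = path,
    pixelPitchMm = pitch,
    scaleFactor = as.integer(scaleFactor),
    frameRows = as.integer(round(height / 0.021) / scaleFactor),
    frameCols = as.integer(round(52 / 0.021 / scaleFactor)),
    frameRateHz = rate,
    descentMPerMin = descent,
    descentPerFrameMm = descent * 1000 / 60 / rate,
    binVolumeL = breadth / 1000 * path / 1000 * 0.1 * 1000,
    lakeDepth = 16.7,
    binHeight = 0.1)
}
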