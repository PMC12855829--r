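#' Generate a stratified lake environment profile
#'
#' Closed-form depth fields for a late-summer stratified temperate lake:
#' a logistic thermocline, a chlorophyll-a field with a deep maximum, a
#' phycoerythrin peak centred below the chlorophyll maximum, and a
#' dissolved-oxygen field that stays above 3 mg/L. Optional seeded noise is
#' applied to the curve parameters (not pointwise), so the structural
#' invariants -- non-increasing temperature, oxygen >= 3 mg/L, chlorophyll
#' peaking shallower than phycoerythrin -- hold for every seed.
#'
#' @param depthGrid depth grid in metres; default 0.5 m steps to 16.5 m,
#'   the cadence of an hourly multiparameter-sonde profile.
#' @param surfaceTemp,bottomTemp epilimnion and hypolimnion temperatures, C.
#' @param thermoclineDepth,thermoclineWidth logistic midpoint and width, m.
#' @param chlBase,chlPeak baseline and deep-maximum amplitude of
#'   chlorophyll-a, ug/L.
#' @param chlPeakDepth,pePeakDepth centre depths of the chlorophyll and
#'   phycoerythrin maxima, m; the phycoerythrin peak must be deeper.
#' @param noiseSd relative jitter applied to the curve parameters (0
#'   disables noise and returns the exact closed-form curves).
#' @param seed integer seed for the parameter jitter.
#' @return an [EnvironmentProfile-class].
#' @examples
#' env <- makeEnvironment(seed = 1)
#' env
#' @export
makeEnvironment <- function(depthGrid = seq(0, 16.5, by = 0.5),
                            surfaceTemp = 19.5, bottomTemp = 7.0,
                            thermoclineDepth = 8.0, thermoclineWidth = 1.3,
                            chlBase = 2.0, chlPeak = 4.5,
                            chlPeakDepth = 9.0, pePeakDepth = 10.8,
                            noiseSd = 0.03, seed = 1L) {
  if (thermoclineDepth < min(depthGrid) || thermoclineDepth > max(depthGrid)) {
    stop("thermoclineDepth must lie inside the depth grid")
  }
  if (pePeakDepth <= chlPeakDepth) {
    stop("the phycoerythrin peak must lie below the chlorophyll-a peak")
  }
  if (noiseSd > 0) {
    jitter <- .withSubstream(seed, "environment", stats::rnorm(8, 0, noiseSd))
    surfaceTemp <- surfaceTemp * (1 + jitter[1])
    bottomTemp <- min(bottomTemp * (1 + jitter[2]), surfaceTemp - 1)
    thermoclineDepth <- min(max(thermoclineDepth * (1 + jitter[3]),
                                min(depthGrid)), max(depthGrid))
    chlBase <- abs(chlBase * (1 + jitter[4]))
    chlPeak <- abs(chlPeak * (1 + jitter[5]))
    chlPeakDepth <- chlPeakDepth * (1 + jitter[6])
    pePeakDepth <- max(pePeakDepth * (1 + jitter[7]),
                       chlPeakDepth + 0.6 + abs(jitter[8]))
  }
  z <- depthGrid
  temp <- bottomTemp + (surfaceTemp - bottomTemp) /
    (1 + exp((z - thermoclineDepth) / thermoclineWidth))
  chl <- chlBase + chlPeak * exp(-(z - chlPeakDepth)^2 / (2 * 1.6^2))
  pe <- 0.5 + 3.0 * exp(-(z - pePeakDepth)^2 / (2 * 1.2^2))
  # well-oxygenated column with a mild metalimnetic dip, floor far above 3
  oxy <- 10.5 - 0.12 * z - 1.2 * exp(-(z - thermoclineDepth)^2 / (2 * 2^2))
  new("EnvironmentProfile", depth = z, temperature = temp, chlA = chl,
      phycoerythrin = pe, oxygen = oxy)
}

#' Depth grid of an environment profile
#' @param x an [EnvironmentProfile-class].
#' @return numeric vector of depths, metres.
#' @export
depthGrid <- function(x) {
  stopifnot(is(x, "EnvironmentProfile"))
  x@depth
}

#' Interpolate environment fields to arbitrary depths
#'
#' Linear interpolation of temperature and chlorophyll-a to the requested
#' depths (constant extrapolation at the ends of the grid).
#'
#' @param x an [EnvironmentProfile-class].
#' @param depth depths in metres.
#' @return data.frame with columns depth, temperature, chl_a.
#' @export
environmentAt <- function(x, depth) {
  stopifnot(is(x, "EnvironmentProfile"))
  data.frame(
    depth = depth,
    temperature = stats::approx(x@depth, x@temperature, xout = depth,
                                rule = 2)$y,
    chl_a = stats::approx(x@depth, x@chlA, xout = depth, rule = 2)$y)
}
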