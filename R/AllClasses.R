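#' @import methods
NULL

#' Sun/Moon sky geometry at an instant
#'
#' Holds the solar and lunar geometry needed to model surface illuminance at
#' one instant and site: altitudes, the lunar phase angle (0 degrees = full
#' moon, 180 = new), the illuminated fraction of the lunar disc, the
#' Earth--Moon distance and the observed cloud cover in oktas.
#'
#' @slot time POSIXct instant (UTC).
#' @slot lat,lon site coordinates, degrees.
#' @slot solarAltitude,lunarAltitude geometric altitudes, degrees.
#' @slot lunarPhaseAngle Sun--Moon phase angle, degrees.
#' @slot illuminatedFraction fraction of the lunar disc illuminated, in [0,1];
#'   always equal to (1 + cos(phase angle)) / 2.
#' @slot lunarDistance Earth--Moon distance, km.
#' @slot cloudOkta cloud cover, integer eighths of sky in 0..8.
#'
#' @seealso [lunarState()], [surfaceIlluminance()]
#' @export
setClass("SkyState", representation(
  time = "POSIXct",
  lat = "numeric",
  lon = "numeric",
  solarAltitude = "numeric",
  lunarAltitude = "numeric",
  lunarPhaseAngle = "numeric",
  illuminatedFraction = "numeric",
  lunarDistance = "numeric",
  cloudOkta = "integer"
))

setValidity("SkyState", function(object) {
  msg <- character()
  f <- object@illuminatedFraction
  if (f < 0 || f > 1) {
    msg <- c(msg, "illuminatedFraction must lie in [0, 1]")
  }
  expected <- (1 + cos(object@lunarPhaseAngle * pi / 180)) / 2
  if (abs(f - expected) > 1e-9) {
    msg <- c(msg, "illuminatedFraction must equal (1 + cos(phase angle)) / 2")
  }
  if (!(object@cloudOkta %in% 0:8)) {
    msg <- c(msg, "cloudOkta must be an integer in 0..8")
  }
  if (abs(object@lat) > 90) msg <- c(msg, "|lat| must be <= 90")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SkyState", function(object) {
  cat("SkyState at", format(object@time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      "UTC\n")
  cat(sprintf("  site: %.3f deg N, %.3f deg E\n", object@lat, object@lon))
  cat(sprintf("  sun: %+.2f deg   moon: %+.2f deg (%.1f%% lit, phase %.1f deg)\n",
              object@solarAltitude, object@lunarAltitude,
              100 * object@illuminatedFraction, object@lunarPhaseAngle))
  cat(sprintf("  moon distance: %.0f km   cloud: %d okta\n",
              object@lunarDistance, object@cloudOkta))
})

#' Underwater illuminance in 10 cm depth bins
#'
#' An exponentially attenuated light profile evaluated at depth-bin midpoints.
#' Bins are half-open `[z, z + h)` from the surface; values below the scotopic
#' detection floor (default 0.001 lx) are reported as exactly zero.
#'
#' @slot binEdges bin edges in metres, length one more than the number of bins.
#' @slot illuminance per-bin illuminance in lux (0 or >= `floorLux`).
#' @slot surfaceLux modelled illuminance just below the surface, lux.
#' @slot kd diffuse attenuation coefficient, 1/m.
#' @slot wavelength nominal monochromatic wavelength (nm) used for
#'   radiometric conversions.
#' @slot floorLux threshold below which illuminance is treated as zero.
#'
#' @seealso [attenuateProfile()], [lightProfileTable()]
#' @export
setClass("LightProfile", representation(
  binEdges = "numeric",
  illuminance = "numeric",
  surfaceLux = "numeric",
  kd = "numeric",
  wavelength = "numeric",
  floorLux = "numeric"
))

setValidity("LightProfile", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@illuminance) + 1L) {
    msg <- c(msg, "binEdges must have length(illuminance) + 1 entries")
  }
  if (is.unsorted(object@binEdges, strictly = TRUE)) {
    msg <- c(msg, "binEdges must be strictly increasing")
  }
  bad <- object@illuminance != 0 & object@illuminance < object@floorLux
  if (any(bad)) {
    msg <- c(msg, "every illuminance value must be 0 or >= floorLux")
  }
  if (object@kd < 0) msg <- c(msg, "kd must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LightProfile", function(object) {
  n <- length(object@illuminance)
  lit <- sum(object@illuminance > 0)
  cat(sprintf("LightProfile: %d bins to %.1f m, surface %.4g lx, Kd %.2f 1/m\n",
              n, max(object@binEdges), object@surfaceLux, object@kd))
  cat(sprintf("  %d bins above the %.3g lx floor\n", lit, object@floorLux))
})

#' Depth-resolved water-column environment
#'
#' Temperature, chlorophyll-a, phycoerythrin and dissolved-oxygen fields on a
#' regular depth grid, structured like a late-summer stratified lake: a
#' logistic thermocline, a deep chlorophyll maximum and a phycoerythrin peak
#' lying below it, and oxygen never dropping below 3 mg/L.
#'
#' @slot depth depth grid, metres (increasing from the surface).
#' @slot temperature water temperature, degrees C (non-increasing with depth).
#' @slot chlA chlorophyll-a, ug/L.
#' @slot phycoerythrin phycoerythrin, relative units.
#' @slot oxygen dissolved oxygen, mg/L (>= 3 everywhere).
#'
#' @seealso [makeEnvironment()]
#' @export
setClass("EnvironmentProfile", representation(
  depth = "numeric",
  temperature = "numeric",
  chlA = "numeric",
  phycoerythrin = "numeric",
  oxygen = "numeric"
))

setValidity("EnvironmentProfile", function(object) {
  msg <- character()
  n <- length(object@depth)
  if (any(lengths(list(object@temperature, object@chlA, object@phycoerythrin,
                       object@oxygen)) != n)) {
    msg <- c(msg, "all fields must match the depth grid length")
  }
  if (is.unsorted(object@depth, strictly = TRUE)) {
    msg <- c(msg, "depth grid must be strictly increasing")
  }
  if (any(diff(object@temperature) > 1e-9)) {
    msg <- c(msg, "temperature must be non-increasing with depth")
  }
  if (any(object@oxygen < 3)) {
    msg <- c(msg, "oxygen must stay >= 3 mg/L")
  }
  if (n > 0L &&
      object@depth[which.max(object@chlA)] >=
      object@depth[which.max(object@phycoerythrin)]) {
    msg <- c(msg, "chlorophyll-a must peak shallower than phycoerythrin")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnvironmentProfile", function(object) {
  cat(sprintf("EnvironmentProfile: %d depths, %.1f-%.1f m\n",
              length(object@depth), min(object@depth), max(object@depth)))
  cat(sprintf("  temperature %.1f -> %.1f C, chl-a peak at %.1f m, PE peak at %.1f m\n",
              object@temperature[1], object@temperature[length(object@depth)],
              object@depth[which.max(object@chlA)],
              object@depth[which.max(object@phycoerythrin)]))
})

#' One shadowgraph frame with depth metadata
#'
#' A single 8-bit grayscale shadowgraph frame. The recorded depth is the depth
#' of the frame's top edge; pixel row 0 is the shallowest row, so a detection
#' at pixel row r sits at `topDepth + r * pixelPitch / 1000` metres.
#'
#' @slot pixels numeric matrix of pixel values in [0, 255] (rows = image
#'   height / depth axis).
#' @slot pixelPitch physical size of one pixel, mm.
#' @slot topDepth depth of the frame's top edge, metres.
#' @slot time acquisition instant, UTC.
#' @slot profileId character profile identifier.
#' @slot frameIndex 0-based frame index within the profile.
#'
#' @seealso [renderProfileFrames()], [flatField()], [binarizeSegment()]
#' @export
setClass("PlanktonFrame", representation(
  pixels = "matrix",
  pixelPitch = "numeric",
  topDepth = "numeric",
  time = "POSIXct",
  profileId = "character",
  frameIndex = "integer"
))

setValidity("PlanktonFrame", function(object) {
  msg <- character()
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  px <- object@pixels
  if (length(px) && (min(px) < 0 || max(px) > 255)) {
    msg <- c(msg, "pixel values must lie in [0, 255]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlanktonFrame", function(object) {
  cat(sprintf("PlanktonFrame %s #%d: %d x %d px at %.3f mm, top depth %.3f m\n",
              object@profileId, object@frameIndex,
              nrow(object@pixels), ncol(object@pixels),
              object@pixelPitch, object@topDepth))
})

#' Fitted gamma log-link mixed model
#'
#' Result of fitting density ~ fixed design with random intercepts for
#' sampling date and profile, a gamma response and log link. Coefficients are
#' on the log-mean scale; `scaling` records the centring/scaling constants
#' applied to continuous covariates so effects remain interpretable.
#'
#' @slot beta named fixed-effect vector, log-mean scale.
#' @slot sigma2Date,sigma2Profile random-intercept variances.
#' @slot shape gamma shape parameter (response variance = mean^2 / shape).
#' @slot loglik maximized log-likelihood.
#' @slot converged logical convergence flag; bootstrap refuses an
#'   unconverged fit.
#' @slot nObs number of rows used (after zero-density handling).
#' @slot nDropped number of zero-density rows dropped before fitting.
#' @slot design design name, "daynight", "night" or "custom".
#' @slot scaling named list of (center, scale) pairs per continuous covariate.
#' @slot X fixed-effect design matrix retained for bootstrap refits.
#' @slot y response vector used in the fit.
#' @slot dateGroup,profileGroup grouping factors (length 0 when absent).
#' @slot engine fitting engine used ("glmmTMB" or "glm").
#'
#' @seealso [fitGammaGlmm()], [parametricBootstrapHpd()], [modelReport()]
#' @export
setClass("GlmmFit", representation(
  beta = "numeric",
  sigma2Date = "numeric",
  sigma2Profile = "numeric",
  shape = "numeric",
  loglik = "numeric",
  converged = "logical",
  nObs = "integer",
  nDropped = "integer",
  design = "character",
  scaling = "list",
  X = "matrix",
  y = "numeric",
  dateGroup = "factor",
  profileGroup = "factor",
  engine = "character"
))

setValidity("GlmmFit", function(object) {
  msg <- character()
  if (object@shape <= 0) msg <- c(msg, "gamma shape must be positive")
  if (object@sigma2Date < 0 || object@sigma2Profile < 0) {
    msg <- c(msg, "random-intercept variances must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GlmmFit", function(object) {
  cat(sprintf("GlmmFit (%s design, %s): %d obs, %d fixed effects\n",
              object@design, object@engine, object@nObs, length(object@beta)))
  cat(sprintf("  sigma2 date %.4f, sigma2 profile %.4f, gamma shape %.3f\n",
              object@sigma2Date, object@sigma2Profile, object@shape))
  cat(sprintf("  logLik %.2f, converged: %s\n", object@loglik,
              object@converged))
})

#' @describeIn GlmmFit fixed-effect coefficients on the log-mean scale.
#' @param object a `GlmmFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "GlmmFit", function(object, ...) object@beta)

#' @describeIn GlmmFit maximized log-likelihood.
#' @export
setMethod("logLik", "GlmmFit", function(object, ...) object@loglik)

#' Parametric-bootstrap HPD confidence intervals
#'
#' Highest-posterior-density (shortest) 95% intervals for fixed effects and
#' random-effect variances, computed from parametric-bootstrap refits. A term
#' is flagged significant when its interval excludes zero.
#'
#' @slot table data.frame with columns term, estimate, hpdLow, hpdHigh,
#'   significant.
#' @slot level interval mass (default 0.95).
#' @slot nIter number of bootstrap refits retained.
#' @slot seed seed used for the bootstrap stream.
#'
#' @seealso [parametricBootstrapHpd()]
#' @export
setClass("BootstrapCI", representation(
  table = "data.frame",
  level = "numeric",
  nIter = "integer",
  seed = "integer"
))

setMethod("show", "BootstrapCI", function(object) {
  cat(sprintf("BootstrapCI: %d terms, %.0f%% HPD from %d refits (seed %d)\n",
              nrow(object@table), 100 * object@level, object@nIter,
              object@seed))
  print(object@table, digits = 3, row.names = FALSE)
})
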