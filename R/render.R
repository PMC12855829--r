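# Shadowgraph frame renderer: bright background with a smooth multiplicative
# illumination field and Gaussian sensor noise; organisms as dark silhouettes
# whose prolate-spheroid ESD equals the ground-truth ESD.

# Fill an ellipse (centre px coords, semi-axes px, angle rad) into `img`
# with anti-aliased edges: boundary pixels take partial darkness
# proportional to their coverage, so sub-pixel sizes survive downscaling.
.drawEllipse <- function(img, cr, cc, a, b, theta, level) {
  rr <- max(1L, floor(cr - a - 2)):min(nrow(img), ceiling(cr + a + 2))
  cols <- max(1L, floor(cc - a - 2)):min(ncol(img), ceiling(cc + a + 2))
  if (!length(rr) || !length(cols)) return(img)
  dr <- rr - cr
  dc <- cols - cc
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr, dc, function(x, y) (x * ct + y * st) / a)
  v <- outer(dr, dc, function(x, y) (-x * st + y * ct) / b)
  rho <- sqrt(u^2 + v^2)
  # signed-distance anti-aliasing: |grad rho| converts the rho-distance to
  # pixel units, so the edge band is one pixel wide everywhere on the
  # boundary (narrower at the tips than at the flanks)
  grad <- sqrt((u / a)^2 + (v / b)^2) / pmax(rho, 1e-9)
  cov <- pmin(1, pmax(0, (1 - rho) / grad + 0.5))
  sub <- img[rr, cols, drop = FALSE]
  shaded <- sub * (1 - cov) + level * cov
  img[rr, cols] <- pmin(sub, shaded)
  img
}

# Thin stroke of physical width `widthPx` (may be < 1: sub-pixel strokes
# darken partially) from (r0,c0) along direction `ang` for `len` pixels.
.drawStroke <- function(img, r0, c0, ang, len, level, widthPx = 1) {
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, len, length.out = n)
  rr <- round(r0 + t * cos(ang))
  cc <- round(c0 + t * sin(ang))
  ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  idx <- unique(cbind(rr[ok], cc[ok]))
  cov <- min(1, widthPx)
  img[idx] <- pmin(img[idx], img[idx] * (1 - cov) + level * cov)
  img
}

#' Default smooth illumination field
#'
#' Multiplicative background illumination across the image field: a linear
#' lateral gradient of the given relative span plus a mild radial falloff,
#' emulating collimator vignetting. Mean is 1.
#'
#' @param nrow,ncol frame dimensions in pixels.
#' @param gradient total relative span of the lateral linear component
#'   (default 0.2, i.e. +-10%).
#' @return matrix of multiplicative factors.
#' @export
illuminationField <- function(nrow, ncol, gradient = 0.2) {
  lat <- matrix(rep(seq(-gradient / 2, gradient / 2, length.out = ncol),
                    each = nrow), nrow, ncol)
  r <- matrix(rep(seq(-1, 1, length.out = nrow), times = ncol), nrow, ncol)
  c2 <- matrix(rep(seq(-1, 1, length.out = ncol), each = nrow), nrow, ncol)
  field <- (1 + lat) * (1 - 0.03 * (r^2 + c2^2))
  field / mean(field)
}

#' Render ground-truth individuals into shadowgraph frames
#'
#' Produces the frame sequence of one descent: frame k spans depths
#' `[k * delta, k * delta + frame height]` with `delta` the descent per frame
#' (34.72 mm at 5 m/min and 2.4 frames/s), so consecutive frames overlap by
#' 8.28 mm. Each individual whose depth falls inside a frame's span is
#' rendered there as a dark silhouette: cladocerans as compact ovoids,
#' copepods as elongated bodies (near-horizontal, so antennae do not bias
#' the depth centroid) with thin antenna strokes at the head and shorter
#' caudal strokes at the tail. Silhouette axes are chosen so the
#' prolate-spheroid ESD `(major * minor^2)^(1/3)` equals `esd_true`.
#'
#' @param individuals data.frame from [placeIndividuals()], sorted by depth.
#' @param optics from [opticsConfig()]; its `scaleFactor` sets the rendered
#'   resolution.
#' @param maxDepth profile bottom depth, m.
#' @param illumination multiplicative illumination matrix (defaults to
#'   [illuminationField()] at the frame size), or NULL for flat.
#' @param noiseSd Gaussian sensor noise SD in 8-bit counts (0 disables).
#' @param seed integer seed (noise and silhouette orientations).
#' @param profileId profile identifier stamped on the frames.
#' @param startTime acquisition time of frame 0 (UTC).
#' @param background,silhouetteLevel background and silhouette grey levels.
#' @return list of [PlanktonFrame-class] objects.
#' @export
renderProfileFrames <- function(individuals, optics = opticsConfig(),
                                maxDepth = optics$lakeDepth,
                                illumination = NULL, noiseSd = 2,
                                seed = 1L, profileId = "profile",
                                startTime = as.POSIXct("2022-08-25 19:00:00",
                                                       tz = "UTC"),
                                background = 230, silhouetteLevel = 45) {
  if (nrow(individuals) && is.unsorted(individuals$depth)) {
    stop("individuals must be sorted by depth")
  }
  if (nrow(individuals) && max(individuals$depth) > maxDepth) {
    stop("individual deeper than the profile bottom")
  }
  pitchM <- optics$pixelPitchMm / 1000
  frameHm <- optics$frameRows * pitchM
  deltaM <- optics$descentPerFrameMm / 1000
  nFrames <- max(1L, as.integer(ceiling((maxDepth - frameHm) / deltaM)) + 1L)
  if (is.null(illumination)) {
    illumination <- illuminationField(optics$frameRows, optics$frameCols)
  }
  base <- background * illumination

  orient <- .withSubstream(seed, "orientation", {
    n <- nrow(individuals)
    ifelse(rep(individuals$antenna, length.out = n),
           stats::runif(n, -20, 20) * pi / 180 + pi / 2,  # near-horizontal
           stats::runif(n, 0, pi))
  })

  frames <- vector("list", nFrames)
  noiseSeed <- .subseed(seed, "noise")
  for (k in seq_len(nFrames) - 1L) {
    top <- k * deltaM
    img <- base
    inFrame <- which(individuals$depth >= top &
                     individuals$depth < top + frameHm)
    for (i in inFrame) {
      esd <- individuals$esd_true[i]
      ratio <- individuals$axis_ratio[i]
      majorMm <- esd * ratio^(2 / 3)
      minorMm <- esd / ratio^(1 / 3)
      a <- majorMm / optics$pixelPitchMm / 2
      b <- minorMm / optics$pixelPitchMm / 2
      cr <- (individuals$depth[i] - top) / pitchM + 0.5
      cc <- individuals$lateral_mm[i] / optics$pixelPitchMm + 0.5
      th <- orient[i]
      img <- .drawEllipse(img, cr, cc, a, b, th, silhouetteLevel)
      if (isTRUE(individuals$antenna[i])) {
        # a pair of thin antenna strokes at the head, angled off the body
        # axis; kept short so ellipse moments stay body-driven
        headR <- cr + a * cos(th); headC <- cc + a * sin(th)
        len <- max(2, 0.5 * a)
        antennaWidthPx <- 0.021 / optics$pixelPitchMm  # ~21 um antennae
        for (s in c(-1, 1)) {
          img <- .drawStroke(img, headR, headC, th + s * 0.5, len,
                             silhouetteLevel, widthPx = antennaWidthPx)
        }
      }
    }
    if (noiseSd > 0) {
      img <- img + .withSubstream(noiseSeed + k, "frame-noise",
        matrix(stats::rnorm(length(img), 0, noiseSd), nrow(img), ncol(img)))
    }
    img <- pmin(pmax(img, 0), 255)
    frames[[k + 1L]] <- new("PlanktonFrame",
      pixels = img, pixelPitch = optics$pixelPitchMm, topDepth = top,
      time = startTime + k / optics$frameRateHz,
      profileId = profileId, frameIndex = k)
  }
  frames
}
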