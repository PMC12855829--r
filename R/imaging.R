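# Detection side of the pipeline: flat-field correction, dark-on-bright
# binarization, 8-connected component labelling, ROI extraction, moment-based
# morphometry with prolate-spheroid ESD, and a pluggable rule-based taxon
# classifier.

.framePixels <- function(frame) {
  if (is(frame, "PlanktonFrame")) frame@pixels else frame
}

#' Per-pixel background reference from a frame window
#'
#' Median of each pixel over a sliding window of frames centred on `index`
#' (default window 21), the standard background estimate for flat-fielding
#' sparse particle imagery.
#'
#' @param frames list of [PlanktonFrame-class] or matrices.
#' @param index frame position the reference is for (default: middle).
#' @param window odd window width in frames.
#' @return background matrix.
#' @export
backgroundReference <- function(frames, index = ceiling(length(frames) / 2),
                                window = 21) {
  half <- window %/% 2
  sel <- max(1, index - half):min(length(frames), index + half)
  mats <- lapply(frames[sel], .framePixels)
  # per-pixel median via a vectorized compare-exchange sorting network
  # (fast for the window sizes used here)
  k <- length(mats)
  if (k == 1) return(mats[[1]])
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(mats[[j]], mats[[j + 1]])
      mats[[j + 1]] <- pmax(mats[[j]], mats[[j + 1]])
      mats[[j]] <- lo
    }
  }
  if (k %% 2 == 1) mats[[(k + 1) / 2]] else
    (mats[[k / 2]] + mats[[k / 2 + 1]]) / 2
}

#' Flat-field correction
#'
#' Divides a frame by a per-pixel background reference, rescales the ratio
#' image to mean 1 and maps it back to 8-bit grey around the reference's
#' mean level, removing smooth illumination structure. Near-idempotent: a
#' second pass against a flat reference changes pixels by well under 1%.
#'
#' @param frame a [PlanktonFrame-class] or matrix.
#' @param reference background matrix (e.g. [backgroundReference()] or a
#'   recorded blank); must be strictly positive.
#' @return corrected frame of the same class as the input.
#' @export
flatField <- function(frame, reference) {
  px <- .framePixels(frame)
  if (any(reference <= 0)) stop("reference must not contain zeros")
  if (!all(dim(px) == dim(reference))) stop("reference dimension mismatch")
  ratio <- px / reference
  ratio <- ratio / mean(ratio)
  out <- pmin(pmax(ratio * mean(px), 0), 255)
  if (is(frame, "PlanktonFrame")) {
    frame@pixels <- out
    frame
  } else {
    out
  }
}

# Merge 4-connected labels that touch diagonally, giving exact 8-connected
# components (vectorized union-find over the label adjacency graph).
.merge8 <- function(lab) {
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  edges <- NULL
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  keep <- a > 0 & b > 0 & a != b
  edges <- rbind(edges, cbind(a[keep], b[keep]))
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  keep <- a > 0 & b > 0 & a != b
  edges <- rbind(edges, cbind(a[keep], b[keep]))
  if (is.null(edges) || nrow(edges) == 0) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Binarize a frame and label connected particles
#'
#' Shadowgraph particles are dark on a bright field: foreground pixels are
#' those darker than (background centre - k * background spread), with the
#' centre and spread estimated robustly by the median and MAD so sparse
#' silhouettes do not bias the threshold. When the background spread is
#' degenerate (zero MAD on a non-constant image) an Otsu threshold is used
#' instead. Components are labelled with 8-connectivity.
#'
#' @param frame a flat-fielded [PlanktonFrame-class] or matrix.
#' @param kSigma threshold distance in background SD units (default 3).
#' @return integer label matrix (0 = background); a blank frame yields all
#'   zeros.
#' @export
binarizeSegment <- function(frame, kSigma = 3) {
  px <- .framePixels(frame)
  # background statistics from a strided subsample on large frames;
  # silhouettes are sparse so median/MAD are insensitive to them
  sub <- if (length(px) > 4e5) {
    px[seq(1L, length(px), length.out = 2e5)]
  } else px
  mu <- stats::median(sub)
  s <- stats::mad(sub)
  if (s == 0) {
    if (min(px) == max(px)) return(matrix(0L, nrow(px), ncol(px)))
    thr <- EBImage::otsu(EBImage::Image(px / 255)) * 255
    mask <- px < thr
  } else {
    mask <- px < mu - kSigma * s
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(px), ncol(px)))
  .merge8(lab)
}

#' Extract region-of-interest vignettes
#'
#' One vignette per labelled component whose pixel area lies within
#' `[minPx, maxPx]`; the bounding box is expanded by `marginPx` and clipped
#' to the frame. The default minimum (50 px at full resolution) keeps the
#' smallest admissible organism (0.36 mm ESD, about 230 px of silhouette at
#' 21 um pitch) with ample margin while rejecting noise specks; scale the
#' thresholds by 1/scaleFactor^2 for downsampled frames.
#'
#' @param labels label matrix from [binarizeSegment()].
#' @param frame matching frame or matrix (for pixel data).
#' @param minPx,maxPx inclusive component-area bounds in pixels.
#' @param marginPx bounding-box margin in pixels.
#' @return list of vignettes, each a list with elements mask (logical
#'   matrix), pixels, offset (top-left row/col in frame coords, 1-based) and
#'   area.
#' @export
extractRois <- function(labels, frame, minPx = 50, maxPx = 500000,
                        marginPx = 5) {
  if (minPx >= maxPx) stop("minPx must be below maxPx")
  px <- .framePixels(frame)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= minPx & areas <= maxPx)
  lapply(keep, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    r0 <- max(1, min(w[, 1]) - marginPx)
    r1 <- min(nrow(px), max(w[, 1]) + marginPx)
    c0 <- max(1, min(w[, 2]) - marginPx)
    c1 <- min(ncol(px), max(w[, 2]) + marginPx)
    list(mask = labels[r0:r1, c0:c1, drop = FALSE] == id,
         pixels = px[r0:r1, c0:c1, drop = FALSE],
         offset = c(row = r0, col = c0),
         area = areas[id])
  })
}

# Convex-hull area of a pixel set (shoelace on the hull of pixel centres,
# plus the half-pixel boundary ring so a single pixel has area ~1).
.hullArea <- function(rc) {
  if (nrow(rc) < 3) return(nrow(rc))
  h <- grDevices::chull(rc)
  pts <- rc[h, , drop = FALSE]
  n <- nrow(pts)
  x <- pts[, 2]; y <- pts[, 1]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(rowSums((pts - pts[c(2:n, 1), , drop = FALSE])^2)))
  area + per / 2 + 1
}

#' Morphometry of one ROI
#'
#' Image moments of the ROI mask give the equivalent-ellipse major and minor
#' axis diameters (4 sqrt of the covariance eigenvalues); the organism's
#' volume is modelled as a prolate spheroid `V = pi/6 * major * minor^2`,
#' so the equivalent spherical diameter is `(major * minor^2)^(1/3)`. Also
#' computes the shape features the classifier uses: aspect ratio, solidity
#' (area over convex-hull area) and the count of thin protrusions (connected
#' pixel groups outside the fitted ellipse, e.g. antennae).
#'
#' @param vignette one element of [extractRois()] output.
#' @param pixelPitch pixel size in mm.
#' @return list with area_px, centroid_row, centroid_col (frame coords),
#'   major_axis_mm, minor_axis_mm, esd_mm, aspect, solidity, protrusions.
#' @examples
#' # a 1.0 x 0.5 mm ellipse has ESD (1.0 * 0.25)^(1/3) = 0.63 mm
#' @export
measureRoi <- function(vignette, pixelPitch = 0.021) {
  mask <- vignette$mask
  if (!any(mask)) stop("empty vignette")
  rc <- which(mask, arr.ind = TRUE)
  n <- nrow(rc)
  # darkness-weighted moments: weighting each foreground pixel by its
  # contrast against the local background recovers sub-pixel (anti-aliased)
  # silhouette extent, which matters for small organisms at coarse pitch
  wts <- rep(1, n)
  weighted <- FALSE
  if (!is.null(vignette$pixels) && any(!mask)) {
    ref <- stats::median(vignette$pixels[!mask])
    w0 <- pmax(ref - vignette$pixels[mask], 0)
    if (sum(w0) > 0) {
      wts <- w0
      weighted <- TRUE
    }
  }
  wts <- wts / sum(wts)
  mu <- colSums(rc * wts)
  d0 <- sweep(rc, 2, mu)
  # weighted pixel-centre sums follow the midpoint rule over the (anti-
  # aliased) intensity profile, so no pixel-variance correction is needed;
  # binary masks get the classic 1/12 unit-pixel term instead
  cv <- crossprod(d0 * sqrt(wts)) +
    if (weighted) diag(0, 2) else diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE)
  majorPx <- 4 * sqrt(ev$values[1])
  minorPx <- 4 * sqrt(ev$values[2])
  major <- majorPx * pixelPitch
  minor <- minorPx * pixelPitch
  # protrusions: pixel groups outside the fitted ellipse inflated by 15%
  ax <- ev$vectors[, 1]
  d <- sweep(rc, 2, mu)
  u <- (d %*% ax) / (1.15 * majorPx / 2)
  v <- (d %*% ev$vectors[, 2]) / (1.15 * minorPx / 2)
  outside <- (u^2 + v^2) > 1
  protr <- 0L
  if (any(outside)) {
    om <- matrix(0, nrow(mask), ncol(mask))
    om[rc[outside, , drop = FALSE]] <- 1
    ol <- .merge8(EBImage::bwlabel(om))
    protr <- sum(tabulate(ol[ol > 0]) >= 2)
  }
  list(area_px = n,
       centroid_row = unname(mu[1]) + vignette$offset[["row"]] - 1,
       centroid_col = unname(mu[2]) + vignette$offset[["col"]] - 1,
       major_axis_mm = major,
       minor_axis_mm = minor,
       esd_mm = (major * minor^2)^(1 / 3),
       aspect = majorPx / minorPx,
       solidity = n / .hullArea(rc),
       protrusions = protr)
}

#' Rule-based taxon classifier
#'
#' Stand-in for a learned classifier, behind the same interface (any
#' function mapping a morphometry list to a taxon and score can replace
#' it): copepod when the aspect ratio reaches 2 or at least two thin
#' protrusions (antennae) are present; cladoceran when the shape is compact
#' (aspect below 2) and solid (solidity at least 0.9); otherwise "other".
#' The score is a margin-based confidence in [0, 1].
#'
#' @param m morphometry list from [measureRoi()].
#' @return list(taxon, score).
#' @export
classifyRoi <- function(m) {
  if (m$aspect >= 2 || m$protrusions >= 2) {
    score <- 0.5 + 0.2 * min((m$aspect - 2) / 1.0 + (m$protrusions >= 2), 2.5)
    list(taxon = "copepod", score = max(0, min(1, score)))
  } else if (m$solidity >= 0.9) {
    score <- 0.5 + 2 * (m$solidity - 0.9) + 0.15 * (2 - m$aspect)
    list(taxon = "cladoceran", score = max(0, min(1, score)))
  } else {
    list(taxon = "other", score = 0.5)
  }
}

#' Drop detections at or below the admissibility ESD
#'
#' Keeps detections strictly larger than `esdMin` (default 0.36 mm, the
#' instrument's practical resolution bound), preserving order; idempotent.
#'
#' @param detections data.frame with an `esd_mm` column.
#' @param esdMin minimum admissible ESD, mm.
#' @return filtered data.frame.
#' @export
filterDetections <- function(detections, esdMin = 0.36) {
  detections[detections$esd_mm > esdMin, , drop = FALSE]
}

#' Detect and measure organisms in one frame
#'
#' Convenience chain for a single frame: optional flat-fielding,
#' binarization/labelling, ROI extraction with area thresholds scaled to
#' the frame's pixel pitch, morphometry and classification.
#'
#' @param frame a [PlanktonFrame-class].
#' @param reference optional background matrix for [flatField()].
#' @param kSigma threshold parameter of [binarizeSegment()].
#' @param minPx,maxPx ROI area bounds at full resolution; they are scaled
#'   by the square of (0.021 / pixel pitch) internally.
#' @param classifier classifier function with the [classifyRoi()] interface.
#' @return data.frame of detections (possibly empty) with columns
#'   profile_id, frame_index, centroid_row, centroid_col, area_px,
#'   major_axis_mm, minor_axis_mm, esd_mm, aspect, solidity, taxon, score,
#'   depth_m.
#' @export
detectFrame <- function(frame, reference = NULL, kSigma = 3,
                        minPx = 50, maxPx = 500000,
                        classifier = classifyRoi) {
  stopifnot(is(frame, "PlanktonFrame"))
  if (!is.null(reference)) frame <- flatField(frame, reference)
  scale2 <- (frame@pixelPitch / 0.021)^2
  lab <- binarizeSegment(frame, kSigma)
  rois <- extractRois(lab, frame, minPx = max(4, minPx / scale2),
                      maxPx = maxPx / scale2)
  empty <- data.frame(profile_id = character(), frame_index = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      area_px = integer(), major_axis_mm = numeric(),
                      minor_axis_mm = numeric(), esd_mm = numeric(),
                      aspect = numeric(), solidity = numeric(),
                      taxon = character(), score = numeric(),
                      depth_m = numeric())
  if (!length(rois)) return(empty)
  rows <- lapply(rois, function(v) {
    m <- measureRoi(v, frame@pixelPitch)
    cl <- classifier(m)
    data.frame(profile_id = frame@profileId,
               frame_index = frame@frameIndex,
               centroid_row = m$centroid_row,
               centroid_col = m$centroid_col,
               area_px = m$area_px,
               major_axis_mm = m$major_axis_mm,
               minor_axis_mm = m$minor_axis_mm,
               esd_mm = m$esd_mm,
               aspect = m$aspect,
               solidity = m$solidity,
               taxon = cl$taxon,
               score = cl$score,
               depth_m = frame@topDepth +
                 (m$centroid_row - 0.5) * frame@pixelPitch / 1000)
  })
  do.call(rbind, rows)
}
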