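# From frame-level detections to the statistics-ready table: de-overlap of
# consecutive frames, size-class assignment, depth binning into densities
# with sampled volumes, covariate attachment, and per-profile depth
# summaries.

#' De-overlap consecutive frame depth spans
#'
#' Consecutive frames overlap whenever the descent per frame is smaller
#' than the frame height (34.72 mm vs 43 mm at the default optics). Each
#' frame keeps the part of its span not already covered by the previous
#' frame's kept strip (keep-first rule): the first strip is the full frame,
#' every later strip starts at the previous strip's bottom. Kept strips are
#' pairwise disjoint half-open intervals whose union is the full profiled
#' span.
#'
#' @param topDepths increasing vector of frame top depths, m.
#' @param frameHeight frame height in m (rows times pitch).
#' @return data.frame with columns frame_index (0-based), strip_top,
#'   strip_bottom (m, half-open `[top, bottom)`).
#' @export
deoverlapFrames <- function(topDepths, frameHeight) {
  if (is.unsorted(topDepths, strictly = TRUE)) {
    stop("frames must be ordered by strictly increasing top depth")
  }
  bottoms <- topDepths + frameHeight
  tops <- c(topDepths[1], pmax(topDepths[-1], bottoms[-length(bottoms)]))
  data.frame(frame_index = seq_along(topDepths) - 1L,
             strip_top = tops, strip_bottom = bottoms)
}

#' Assign an ESD to a size class
#'
#' Closed-interval membership in the per-taxon size-class ranges; ESD
#' values falling in the gaps between ranges are "unclassified" and are
#' excluded from model rows (they are tallied by [binDensities()]).
#'
#' @param esdMm equivalent spherical diameter, mm; vectorized.
#' @param taxon "cladoceran" or "copepod" (scalar or vector).
#' @return character vector: "small", "medium", "large" or "unclassified".
#' @export
assignSizeClass <- function(esdMm, taxon) {
  taxon <- rep(as.character(taxon), length.out = length(esdMm))
  bad <- !taxon %in% c("cladoceran", "copepod")
  if (any(bad)) stop("unknown taxon: ", paste(unique(taxon[bad]),
                                              collapse = ", "))
  out <- rep("unclassified", length(esdMm))
  for (tx in unique(taxon)) {
    rg <- sizeClassRanges(tx)
    sel <- taxon == tx
    for (cls in rownames(rg)) {
      hit <- sel & esdMm >= rg[cls, "lo"] & esdMm <= rg[cls, "hi"]
      out[hit] <- cls
    }
  }
  out
}

#' Depth-bin densities from detections
#'
#' Bins retained detections into half-open 10 cm depth bins `[z, z + 0.1)`
#' and converts counts to densities using the actually sampled volume: the
#' imaged aperture (52 mm breadth x 100 mm path) times the total kept-strip
#' length intersecting each bin. Detections falling outside their frame's
#' kept strip are dropped as duplicates first; detections with taxon
#' "other" or an unclassified size are excluded and tallied. Every covered
#' bin emits one row per taxon x size class (zero counts give density 0);
#' bins with no kept coverage emit no row.
#'
#' @param detections data.frame from [detectFrame()] (after
#'   [filterDetections()]); needs profile_id, frame_index, depth_m, taxon
#'   and either a size_class column or esd_mm (classes are assigned from
#'   ESD when absent).
#' @param strips data.frame from [deoverlapFrames()] for this profile.
#' @param optics from [opticsConfig()].
#' @param lakeDepth,binHeight water column depth and bin height, m.
#' @return data.frame with columns profile_id, taxon, size_class,
#'   bin_index, bin_mid_depth, count, sampled_volume_L, density;
#'   attribute "audit" counts excluded detections.
#' @examples
#' # one detection in a fully covered bin: density 1 / 0.52 L = 1.92 ind/L
#' @export
binDensities <- function(detections, strips, optics = opticsConfig(),
                         lakeDepth = 16.7, binHeight = 0.1) {
  edges <- seq(0, lakeDepth, by = binHeight)
  nBins <- length(edges) - 1L
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  # per-bin kept coverage length (m)
  cover <- numeric(nBins)
  for (i in seq_len(nrow(strips))) {
    lo <- pmin(pmax(strips$strip_top[i], edges[-length(edges)]), edges[-1])
    hi <- pmin(pmax(strips$strip_bottom[i], edges[-length(edges)]), edges[-1])
    cover <- cover + (hi - lo)
  }
  volume <- optics$frameBreadthMm / 1000 * optics$pathLengthMm / 1000 *
    cover * 1000  # litres

  det <- detections
  audit <- c(duplicates = 0L, other_taxon = 0L, unclassified = 0L)
  if (nrow(det)) {
    # keep-first de-overlap: a detection survives only inside its own
    # frame's kept strip
    m <- match(det$frame_index, strips$frame_index)
    keep <- !is.na(m) & det$depth_m >= strips$strip_top[m] &
      det$depth_m < strips$strip_bottom[m]
    audit["duplicates"] <- sum(!keep)
    det <- det[keep, , drop = FALSE]
  }
  if (nrow(det) && is.null(det$size_class)) {
    det$size_class <- rep("unclassified", nrow(det))
    known <- det$taxon %in% c("cladoceran", "copepod")
    det$size_class[known] <- assignSizeClass(det$esd_mm[known],
                                             det$taxon[known])
  }
  if (nrow(det)) {
    other <- !det$taxon %in% c("cladoceran", "copepod")
    audit["other_taxon"] <- sum(other)
    det <- det[!other, , drop = FALSE]
    uncl <- det$size_class == "unclassified"
    audit["unclassified"] <- sum(uncl)
    det <- det[!uncl, , drop = FALSE]
  }

  covered <- which(cover > 0)
  grid <- expand.grid(bin_index = covered - 1L,
                      taxon = c("cladoceran", "copepod"),
                      size_class = .sizeLevels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts <- integer(nrow(grid))
  if (nrow(det)) {
    binIdx <- findInterval(det$depth_m, edges, rightmost.closed = FALSE,
                           left.open = FALSE) - 1L
    inCol <- binIdx >= 0 & binIdx < nBins
    if (any(!inCol)) det <- det[inCol, , drop = FALSE]
    binIdx <- binIdx[inCol]
    if (any(cover[binIdx + 1L] <= 0)) {
      stop("detection in a bin with zero kept coverage")
    }
    key <- paste(binIdx, det$taxon, det$size_class)
    tab <- table(key)
    gkey <- paste(grid$bin_index, grid$taxon, grid$size_class)
    counts <- as.integer(ifelse(gkey %in% names(tab), tab[gkey], 0L))
  }
  out <- data.frame(
    profile_id = if (nrow(detections)) detections$profile_id[1] else
      "profile",
    taxon = grid$taxon,
    size_class = factor(grid$size_class, levels = .sizeLevels),
    bin_index = grid$bin_index,
    bin_mid_depth = mids[grid$bin_index + 1L],
    count = counts,
    sampled_volume_L = volume[grid$bin_index + 1L],
    density = counts / volume[grid$bin_index + 1L])
  attr(out, "audit") <- audit
  out
}

#' Attach light and environment covariates to bin rows
#'
#' Joins per-bin illuminance by bin index (floored values enter as exact
#' zeros) and linearly interpolates temperature and chlorophyll-a to the
#' bin midpoints. The environment grid may stop up to half a metre short
#' of the deepest bin (sonde casts typically end just above the bottom);
#' the end values are extended, anything worse is an error.
#'
#' @param bins output of [binDensities()].
#' @param environment an [EnvironmentProfile-class].
#' @param light a [LightProfile-class] on the same bin grid.
#' @return `bins` with columns illuminance_lx, temperature_C, chl_a_ugL
#'   added; row count unchanged.
#' @export
attachCovariates <- function(bins, environment, light) {
  stopifnot(is(environment, "EnvironmentProfile"), is(light, "LightProfile"))
  if (max(environment@depth) < max(bins$bin_mid_depth) - 0.5) {
    stop("environment grid does not span the profiled depths")
  }
  lx <- illuminance(light)
  if (max(bins$bin_index) + 1L > length(lx)) {
    stop("light profile does not span the profiled bins")
  }
  env <- environmentAt(environment, bins$bin_mid_depth)
  bins$illuminance_lx <- lx[bins$bin_index + 1L]
  bins$temperature_C <- env$temperature
  bins$chl_a_ugL <- env$chl_a
  bins
}

#' Per-profile mean depth of individuals
#'
#' Mean and standard error (SD / sqrt(n)) of the actual depths of the
#' identified individuals, per profile and taxon -- the quantity used for
#' time-series summaries, computed from individual detections rather than
#' binned densities. A single detection yields SE 0; groups with no
#' detections emit no row.
#'
#' @param detections data.frame with profile_id, taxon, depth_m.
#' @return data.frame with profile_id, taxon, mean_depth, se_depth, n.
#' @export
profileMeanDepth <- function(detections) {
  if (!nrow(detections)) {
    return(data.frame(profile_id = character(), taxon = character(),
                      mean_depth = numeric(), se_depth = numeric(),
                      n = integer()))
  }
  sp <- split(detections,
              list(detections$profile_id, detections$taxon), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(profile_id = d$profile_id[1], taxon = d$taxon[1],
               mean_depth = mean(d$depth_m),
               se_depth = if (n > 1) stats::sd(d$depth_m) / sqrt(n) else 0,
               n = n)
  }))
  rownames(out) <- NULL
  out[order(out$profile_id, out$taxon), , drop = FALSE]
}
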