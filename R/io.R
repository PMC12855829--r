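# Readers and writers for the pipeline artifacts: 8-bit grayscale PNG
# frames with a sidecar metadata CSV, and plain CSV for all tables.

#' Write frames as 8-bit grayscale PNG with a sidecar CSV
#'
#' Files are named `{profile_id}_{frame_index:05d}.png`; the sidecar
#' `{profile_id}_frames.csv` records frame_index, top_depth_m, time_utc and
#' pixel_pitch_mm, and is kept in sync with the image files.
#'
#' @param frames list of [PlanktonFrame-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
writeFrames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pid <- frames[[1]]@profileId
  meta <- do.call(rbind, lapply(frames, function(f) {
    png::writePNG(f@pixels / 255,
                  file.path(dir, sprintf("%s_%05d.png", pid, f@frameIndex)))
    data.frame(frame_index = f@frameIndex,
               top_depth_m = f@topDepth,
               time_utc = format(f@time, "%Y-%m-%dT%H:%M:%OS3Z",
                                 tz = "UTC"),
               pixel_pitch_mm = f@pixelPitch)
  }))
  sidecar <- file.path(dir, paste0(pid, "_frames.csv"))
  utils::write.csv(meta, sidecar, row.names = FALSE)
  invisible(sidecar)
}

#' Read frames written by [writeFrames()]
#'
#' @param dir directory holding the PNGs and sidecar CSV.
#' @param profileId profile identifier.
#' @return list of [PlanktonFrame-class].
#' @export
readFrames <- function(dir, profileId) {
  sidecar <- file.path(dir, paste0(profileId, "_frames.csv"))
  if (!file.exists(sidecar)) stop("missing sidecar file: ", sidecar)
  meta <- utils::read.csv(sidecar)
  lapply(seq_len(nrow(meta)), function(i) {
    path <- file.path(dir, sprintf("%s_%05d.png", profileId,
                                   meta$frame_index[i]))
    if (!file.exists(path)) stop("sidecar out of sync; missing ", path)
    px <- png::readPNG(path) * 255
    if (length(dim(px)) == 3) px <- px[, , 1]
    new("PlanktonFrame", pixels = px,
        pixelPitch = meta$pixel_pitch_mm[i],
        topDepth = meta$top_depth_m[i],
        time = as.POSIXct(meta$time_utc[i],
                          format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
        profileId = profileId, frameIndex = as.integer(meta$frame_index[i]))
  })
}

#' Write a pipeline table as CSV
#'
#' Numeric columns keep 15 significant digits so a write/read round trip
#' preserves values to the tolerance the pipeline contracts assume.
#'
#' @param tab data.frame.
#' @param path output path.
#' @param requiredColumns optional character vector validated before
#'   writing.
#' @return invisibly, `path`.
#' @export
writeTableCsv <- function(tab, path, requiredColumns = NULL) {
  if (!is.null(requiredColumns)) {
    miss <- setdiff(requiredColumns, names(tab))
    if (length(miss)) stop("table is missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(tab)) {
    if (inherits(tab[[j]], "POSIXct")) {
      tab[[j]] <- format(tab[[j]], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    }
  }
  # write.table renders numerics via as.character (15 significant digits),
  # enough for the round-trip contract
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, validating its schema
#'
#' @param path CSV path.
#' @param requiredColumns columns that must be present; an informative
#'   schema error lists anything missing.
#' @return data.frame.
#' @export
readTableCsv <- function(path, requiredColumns = NULL) {
  if (!file.exists(path)) stop("missing table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(requiredColumns)) {
    miss <- setdiff(requiredColumns, names(tab))
    if (length(miss)) {
      stop("schema mismatch in ", path, ": missing column(s) ",
           paste(miss, collapse = ", "))
    }
  }
  tab
}
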