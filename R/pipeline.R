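# End-to-end orchestration: configuration, stage execution, manifest and
# logging, plus the imaging-side profile processors shared by tests and
# the acceptance harness.

#' Ground-truth individuals from a target depth distribution
#'
#' Generates one profile's organisms directly from a truncated-normal depth
#' distribution on [0, lakeDepth] -- the generator mode used to emulate a
#' reported daytime depth summary (mean and SD of individual depths)
#' without going through the density field. Sizes are drawn uniformly over
#' the taxon's size-class ranges (classes equiprobable).
#'
#' @param n number of individuals.
#' @param meanDepth,sdDepth parameters of the untruncated normal, m.
#' @param taxon "cladoceran" or "copepod".
#' @param optics from [opticsConfig()].
#' @param lakeDepth truncation bound, m.
#' @param seed integer seed.
#' @return data.frame in the [placeIndividuals()] layout, sorted by depth.
#' @export
simulateDepthDistributedIndividuals <- function(n, meanDepth = 9.13,
                                                sdDepth = 4.24,
                                                taxon = c("cladoceran",
                                                          "copepod"),
                                                optics = opticsConfig(),
                                                lakeDepth = optics$lakeDepth,
                                                seed = 1L) {
  taxon <- match.arg(taxon)
  ranges <- sizeClassRanges(taxon)
  .withSubstream(seed, "depth-individuals", {
    pa <- stats::pnorm(0, meanDepth, sdDepth)
    pb <- stats::pnorm(lakeDepth, meanDepth, sdDepth)
    depth <- stats::qnorm(stats::runif(n, pa, pb), meanDepth, sdDepth)
    cls <- sample(rownames(ranges), n, replace = TRUE)
    out <- data.frame(
      profile_id = "truncnorm",
      taxon = taxon,
      size_class = cls,
      depth = depth,
      esd_true = stats::runif(n, ranges[cls, "lo"], ranges[cls, "hi"]),
      lateral_mm = stats::runif(n, 0, optics$frameBreadthMm),
      axis_ratio = if (taxon == "copepod") stats::runif(n, 2.2, 3.0)
                   else stats::runif(n, 1.2, 1.8),
      antenna = rep(taxon == "copepod", n))
    out[order(out$depth), , drop = FALSE]
  })
}

#' Segment a whole profile of frames
#'
#' Runs detection over every frame (optionally flat-fielding against a
#' median background reference built from a subsample of the profile's own
#' frames), applies the admissibility ESD filter, and removes duplicate
#' detections in frame overlaps via the keep-first de-overlap rule.
#'
#' @param frames list of [PlanktonFrame-class], ordered by depth.
#' @param flatfield logical; estimate a background reference and divide it
#'   out first.
#' @param referenceEvery subsampling stride for the background estimate.
#' @param kSigma binarization threshold parameter.
#' @param esdMin admissibility bound, mm.
#' @param classifier classifier with the [classifyRoi()] interface.
#' @return list with elements detections (de-duplicated, filtered) and
#'   strips (from [deoverlapFrames()]).
#' @export
processProfileFrames <- function(frames, flatfield = TRUE,
                                 referenceEvery = 25, kSigma = 3,
                                 esdMin = 0.36, classifier = classifyRoi) {
  tops <- vapply(frames, function(f) f@topDepth, numeric(1))
  pitchM <- frames[[1]]@pixelPitch / 1000
  frameH <- nrow(frames[[1]]@pixels) * pitchM
  strips <- deoverlapFrames(tops, frameH)
  ref <- NULL
  if (flatfield) {
    sub <- frames[seq(1, length(frames), by = referenceEvery)]
    ref <- backgroundReference(sub, index = ceiling(length(sub) / 2),
                               window = length(sub))
  }
  det <- do.call(rbind, lapply(frames, detectFrame, reference = ref,
                               kSigma = kSigma))
  det <- filterDetections(det, esdMin)
  if (nrow(det)) {
    m <- match(det$frame_index, strips$frame_index)
    keep <- det$depth_m >= strips$strip_top[m] &
      det$depth_m < strips$strip_bottom[m]
    det <- det[keep, , drop = FALSE]
  }
  list(detections = det, strips = strips)
}

#' Default pipeline configuration
#'
#' @param seed root seed fanned out to per-stage substreams.
#' @param outdir output directory for all artifacts.
#' @param nProfiles night profiles in the simulated design.
#' @param renderProfiles how many of them to render and segment.
#' @param scaleFactor frame downscaling factor (1, 2, 4, 8).
#' @param taxon taxon simulated in individual mode.
#' @param design statistical design to fit ("night" or "daynight").
#' @param nBootstrap bootstrap iterations for the report stage.
#' @param kdPerM diffuse attenuation coefficient.
#' @param noiseSd render noise SD, 8-bit counts.
#' @param stages stages to run, a subset of simulate, render, segment,
#'   assemble, fit, report.
#' @return config list.
#' @export
runConfig <- function(seed = 1L, outdir = tempfile("dvmrun"),
                      nProfiles = 4L, renderProfiles = 1L,
                      scaleFactor = 8L, taxon = "cladoceran",
                      design = "night", nBootstrap = 50L, kdPerM = 0.25,
                      noiseSd = 2,
                      stages = c("simulate", "render", "segment",
                                 "assemble", "fit", "report")) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              nProfiles = as.integer(nProfiles),
              renderProfiles = as.integer(renderProfiles),
              scaleFactor = as.integer(scaleFactor), taxon = taxon,
              design = design, nBootstrap = as.integer(nBootstrap),
              kdPerM = kdPerM, noiseSd = noiseSd, stages = stages)
  .validateConfig(cfg)
  cfg
}

.configKeys <- c("seed", "outdir", "nProfiles", "renderProfiles",
                 "scaleFactor", "taxon", "design", "nBootstrap", "kdPerM",
                 "noiseSd", "stages")

.validateConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown)) stop("invalid config key(s): ",
                            paste(unknown, collapse = ", "))
  stopifnot(cfg$scaleFactor %in% c(1L, 2L, 4L, 8L))
  bad <- setdiff(cfg$stages, c("simulate", "render", "segment", "assemble",
                               "fit", "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys take the [runConfig()] defaults; unknown keys are an
#' error naming the key.
#'
#' @param path YAML file.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .configKeys)
  if (length(unknown)) stop("invalid config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

.log <- function(logPath, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%OS1 "), ...)
  cat(line, "\n", file = logPath, append = TRUE)
  message(line)
}

#' Run the pipeline end to end
#'
#' Executes the selected stages -- simulate (design table and gamma
#' densities), render (ground-truth individuals to PNG frames), segment
#' (detection), assemble (de-overlap, binning, covariates, mean depths),
#' fit (gamma mixed model on the simulated density table) and report
#' (bootstrap HPD intervals) -- writing every artifact, a manifest echoing
#' the resolved configuration, and a log under `cfg$outdir`. Later stages
#' read the CSV artifacts of earlier ones, so a stage can be re-run alone
#' provided its inputs exist (a missing input is an error naming the file).
#'
#' @param cfg configuration from [runConfig()] or [readRunConfig()].
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(cfg = runConfig()) {
  .validateConfig(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outdir, "pipeline.log")
  paths <- list(
    manifest = file.path(cfg$outdir, "manifest.yaml"),
    bins = file.path(cfg$outdir, "bin_densities.csv"),
    light = file.path(cfg$outdir, "light_profiles.csv"),
    truth = file.path(cfg$outdir, "true_individuals.csv"),
    frames = file.path(cfg$outdir, "frames"),
    detections = file.path(cfg$outdir, "detections.csv"),
    assembled = file.path(cfg$outdir, "assembled_bins.csv"),
    meanDepth = file.path(cfg$outdir, "profile_mean_depth.csv"),
    fit = file.path(cfg$outdir, "fit.yaml"),
    report = file.path(cfg$outdir, "model_report.csv"))
  yaml::write_yaml(cfg, paths$manifest)
  optics <- opticsConfig(cfg$scaleFactor)

  if ("simulate" %in% cfg$stages) {
    .log(logPath, "simulate: ", cfg$nProfiles, " profiles (", cfg$taxon, ")")
    tab <- nightDesignTable(nProfiles = cfg$nProfiles, kdPerM = cfg$kdPerM,
                            seed = cfg$seed)
    sim <- simulateBinDensities(tab, nightEffectDefaults(cfg$taxon),
                                seed = cfg$seed)
    writeTableCsv(sim, paths$bins)
    lightTab <- do.call(rbind, lapply(split(sim, sim$profile_id),
      function(d) {
        data.frame(profile_id = d$profile_id[1],
                   bin_index = d$bin_index[!duplicated(d$bin_index)],
                   bin_mid_depth_m = d$bin_mid_depth[!duplicated(d$bin_index)],
                   illuminance_lx = d$illuminance_lx[!duplicated(d$bin_index)])
      }))
    writeTableCsv(lightTab, paths$light)
  }

  if ("render" %in% cfg$stages) {
    if (!file.exists(paths$bins)) {
      stop("stage 'render' needs the simulated bin table: ", paths$bins)
    }
    sim <- readTableCsv(paths$bins, c("profile_id", "size_class",
                                      "bin_index", "bin_mid_depth",
                                      "density"))
    ids <- unique(sim$profile_id)[seq_len(min(cfg$renderProfiles,
                                              length(unique(sim$profile_id))))]
    truth <- NULL
    for (pid in ids) {
      ind <- placeIndividuals(sim[sim$profile_id == pid, ],
                              taxon = cfg$taxon, optics = optics,
                              seed = .subseed(cfg$seed, pid))
      ind <- ind[order(ind$depth), , drop = FALSE]
      frames <- renderProfileFrames(ind, optics, noiseSd = cfg$noiseSd,
                                    seed = .subseed(cfg$seed, pid),
                                    profileId = pid)
      writeFrames(frames, paths$frames)
      truth <- rbind(truth, ind)
      .log(logPath, "render: ", pid, " -> ", length(frames), " frames, ",
           nrow(ind), " individuals")
    }
    writeTableCsv(truth, paths$truth)
  }

  if ("segment" %in% cfg$stages) {
    if (!file.exists(paths$truth)) {
      stop("stage 'segment' needs rendered frames: ", paths$truth)
    }
    truth <- readTableCsv(paths$truth)
    det <- NULL
    for (pid in unique(truth$profile_id)) {
      frames <- readFrames(paths$frames, pid)
      res <- processProfileFrames(frames)
      det <- rbind(det, res$detections)
      .log(logPath, "segment: ", pid, " -> ", nrow(res$detections),
           " detections")
    }
    writeTableCsv(det, paths$detections)
  }

  if ("assemble" %in% cfg$stages) {
    if (!file.exists(paths$detections)) {
      stop("stage 'assemble' needs the detections table: ",
           paths$detections)
    }
    det <- readTableCsv(paths$detections, c("profile_id", "frame_index",
                                            "esd_mm", "taxon", "depth_m"))
    assembled <- NULL
    for (pid in unique(det$profile_id)) {
      d <- det[det$profile_id == pid, ]
      tops <- (0:max(d$frame_index)) * optics$descentPerFrameMm / 1000
      strips <- deoverlapFrames(tops, optics$frameRows *
                                  optics$pixelPitchMm / 1000)
      bins <- binDensities(d, strips, optics)
      env <- makeEnvironment(seed = .subseed(cfg$seed, "env1"))
      sky <- lunarState(as.POSIXct("2022-08-25 21:00:00", tz = "UTC"),
                        53.15, 13.03)
      light <- attenuateProfile(surfaceIlluminance(sky), cfg$kdPerM)
      bins <- attachCovariates(bins, env, light)
      assembled <- rbind(assembled, bins)
    }
    writeTableCsv(assembled, paths$assembled)
    writeTableCsv(profileMeanDepth(det), paths$meanDepth)
    .log(logPath, "assemble: ", nrow(assembled), " bin rows")
  }

  fit <- NULL
  if ("fit" %in% cfg$stages) {
    if (!file.exists(paths$bins)) {
      stop("stage 'fit' needs the bin-density table: ", paths$bins)
    }
    sim <- readTableCsv(paths$bins, c("density", "size_class",
                                      "illuminance_lx", "profile_id"))
    fit <- fitBinTable(sim, design = cfg$design)
    yaml::write_yaml(list(beta = as.list(coef(fit)),
                          sigma2_date = fit@sigma2Date,
                          sigma2_profile = fit@sigma2Profile,
                          gamma_shape = fit@shape,
                          loglik = fit@loglik,
                          converged = fit@converged,
                          n_obs = fit@nObs,
                          n_dropped = fit@nDropped,
                          seed = cfg$seed,
                          scaling = lapply(fit@scaling, as.list)),
                     paths$fit)
    .log(logPath, "fit: ", fit@nObs, " rows, converged ", fit@converged)
  }

  if ("report" %in% cfg$stages) {
    if (is.null(fit)) {
      if (!file.exists(paths$bins)) {
        stop("stage 'report' needs the bin-density table: ", paths$bins)
      }
      sim <- readTableCsv(paths$bins, c("density", "size_class",
                                        "illuminance_lx", "profile_id"))
      fit <- fitBinTable(sim, design = cfg$design)
    }
    ci <- parametricBootstrapHpd(fit, nIter = cfg$nBootstrap,
                                 seed = cfg$seed)
    writeTableCsv(modelReport(fit, ci), paths$report)
    .log(logPath, "report: ", cfg$nBootstrap, " bootstrap iterations")
  }

  invisible(paths)
}
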