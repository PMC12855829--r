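# Generative side of the bin-density model: build covariate design tables on
# the profile x depth-bin x size-class grid, draw gamma densities whose
# log-mean follows the mixed-model designs, and turn densities into countable
# individuals.

.sizeLevels <- c("small", "medium", "large")

# Standard campaign dates: two new-moon and two full-moon nights spanning
# two lunar cycles, with the seasonal cooling and deepening mixed layer of
# a temperate lake from late August to mid-October (this across-night
# environmental contrast is what identifies the light x environment
# interactions, since moonlight only reaches the epilimnion).
.campaignDates <- function() {
  data.frame(date = as.Date(c("2022-08-25", "2022-09-13",
                              "2022-09-29", "2022-10-12")),
             moon = c("new", "full", "new", "full"),
             surfaceTemp = c(21.0, 18.5, 16.0, 13.5),
             thermoclineDepth = c(7.0, 8.0, 9.0, 10.0),
             chlBase = c(2.6, 2.1, 1.8, 1.4),
             chlPeak = c(5.0, 4.5, 3.8, 3.2),
             chlPeakDepth = c(8.5, 9.0, 9.6, 10.2))
}

# Environment for campaign night i, jittered by the seed.
.campaignEnvironment <- function(dates, i, seed) {
  makeEnvironment(
    surfaceTemp = dates$surfaceTemp[i],
    bottomTemp = 7.0,
    thermoclineDepth = dates$thermoclineDepth[i],
    chlBase = dates$chlBase[i], chlPeak = dates$chlPeak[i],
    chlPeakDepth = dates$chlPeakDepth[i],
    pePeakDepth = dates$chlPeakDepth[i] + 1.8,
    seed = .subseed(seed, paste0("env", i)))
}

#' Build the covariate table for the night design
#'
#' Lays out the profile x 10 cm bin x size class grid for the night model and
#' attaches physically structured covariates: per-bin illuminance from the
#' sky model attenuated through the water column at each profile's time, and
#' temperature and chlorophyll-a interpolated from a seeded environment
#' profile per date. Profiles are spread over the campaign's four nights
#' (two new-moon, two full-moon) at half-hourly cadence after sunset.
#'
#' @param nProfiles number of night profiles (default 54).
#' @param lakeDepth,binHeight water-column depth and bin height, m.
#' @param lat,lon site coordinates, degrees.
#' @param kdPerM diffuse attenuation coefficient for the underwater light.
#' @param seed integer seed for the environment jitter.
#' @return data.frame with one row per profile x bin x size class: columns
#'   profile_id, date, time, size_class, bin_index, bin_mid_depth,
#'   illuminance_lx, temperature_C, chl_a_ugL.
#' @export
nightDesignTable <- function(nProfiles = 54, lakeDepth = 16.7,
                             binHeight = 0.1, lat = 53.15, lon = 13.03,
                             kdPerM = 0.25, seed = 1L) {
  dates <- .campaignDates()
  perDate <- diff(round(seq(0, nProfiles, length.out = nrow(dates) + 1)))
  edges <- seq(0, lakeDepth, by = binHeight)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  rows <- vector("list", nrow(dates))
  for (i in seq_len(nrow(dates))) {
    if (perDate[i] == 0L) next
    env <- .campaignEnvironment(dates, i, seed)
    at <- environmentAt(env, mids)
    sunset <- .sunsetUtc(dates$date[i], lat, lon)
    # the night model covers profiles after civil twilight only: start the
    # series at the first half-hourly tick with the sun below -6 degrees
    ticks <- sunset + 1800 * (1:24)
    dark <- ticks[solarAltitude(ticks, lat, lon) < -6]
    times <- dark[1] + 1800 * (seq_len(perDate[i]) - 1)
    lux <- vapply(times, function(tm) {
      sky <- lunarState(tm, lat, lon)
      illuminance(attenuateProfile(surfaceIlluminance(sky), kdPerM,
                                   binEdges = edges))
    }, numeric(length(mids)))
    grid <- expand.grid(bin_index = seq_along(mids) - 1L,
                        profile = seq_along(times),
                        size_class = .sizeLevels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      profile_id = sprintf("%s_n%02d", format(dates$date[i], "%Y%m%d"),
                           grid$profile),
      date = format(dates$date[i]),
      time = times[grid$profile],
      size_class = grid$size_class,
      bin_index = grid$bin_index,
      bin_mid_depth = mids[grid$bin_index + 1L],
      illuminance_lx = lux[cbind(grid$bin_index + 1L, grid$profile)],
      temperature_C = at$temperature[grid$bin_index + 1L],
      chl_a_ugL = at$chl_a[grid$bin_index + 1L])
  }
  out <- do.call(rbind, rows)
  out$size_class <- factor(out$size_class, levels = .sizeLevels)
  rownames(out) <- NULL
  out
}

#' Build the covariate table for the day--night design
#'
#' Same grid layout as [nightDesignTable()] but spanning the full day-to-
#' night light range: each campaign date contributes one daytime profile
#' (16:00 CET) plus its night series, up to `nProfiles` in total. Daytime
#' underwater illuminance comes from the solar curve and is capped at
#' `dayLuxCap` so the per-lux slopes of the day--night model stay
#' numerically well-conditioned.
#'
#' @inheritParams nightDesignTable
#' @param nProfiles total number of profiles including the day profiles
#'   (default 70).
#' @param dayLuxCap cap on underwater daytime illuminance, lux.
#' @return data.frame as [nightDesignTable()] plus a `label` column
#'   ("day"/"night").
#' @export
dayNightDesignTable <- function(nProfiles = 70, lakeDepth = 16.7,
                                binHeight = 0.1, lat = 53.15, lon = 13.03,
                                kdPerM = 0.25, dayLuxCap = 50000,
                                seed = 1L) {
  dates <- .campaignDates()
  nightPer <- diff(round(seq(0, nProfiles - nrow(dates),
                             length.out = nrow(dates) + 1)))
  edges <- seq(0, lakeDepth, by = binHeight)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  rows <- vector("list", nrow(dates))
  for (i in seq_len(nrow(dates))) {
    env <- .campaignEnvironment(dates, i, seed)
    at <- environmentAt(env, mids)
    sunset <- .sunsetUtc(dates$date[i], lat, lon)
    dayTime <- as.POSIXct(paste(format(dates$date[i]), "15:00:00"),
                          tz = "UTC")
    times <- c(dayTime, sunset + 1800 * seq_len(nightPer[i]))
    labels <- c("day", rep("night", nightPer[i]))
    ids <- c(sprintf("%s_day", format(dates$date[i], "%Y%m%d")),
             sprintf("%s_n%02d", format(dates$date[i], "%Y%m%d"),
                     seq_len(nightPer[i])))
    lux <- vapply(times, function(tm) {
      sky <- lunarState(tm, lat, lon)
      e <- illuminance(attenuateProfile(surfaceIlluminance(sky), kdPerM,
                                        binEdges = edges))
      pmin(e, dayLuxCap)
    }, numeric(length(mids)))
    grid <- expand.grid(bin_index = seq_along(mids) - 1L,
                        profile = seq_along(times),
                        size_class = .sizeLevels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      profile_id = ids[grid$profile],
      date = format(dates$date[i]),
      time = times[grid$profile],
      label = labels[grid$profile],
      size_class = grid$size_class,
      bin_index = grid$bin_index,
      bin_mid_depth = mids[grid$bin_index + 1L],
      illuminance_lx = lux[cbind(grid$bin_index + 1L, grid$profile)],
      temperature_C = at$temperature[grid$bin_index + 1L],
      chl_a_ugL = at$chl_a[grid$bin_index + 1L])
  }
  out <- do.call(rbind, rows)
  out$size_class <- factor(out$size_class, levels = .sizeLevels)
  rownames(out) <- NULL
  out
}

# Fixed-effect model matrix in the canonical (reported) column order.
.designMatrix <- function(tab, design = c("night", "daynight"),
                          standardize = (design == "night")) {
  design <- match.arg(design)
  d <- data.frame(
    lx = tab$illuminance_lx,
    size = factor(tab$size_class, levels = .sizeLevels))
  scaling <- list()
  if (design == "night") {
    d$temp <- tab$temperature_C
    d$chl <- tab$chl_a_ugL
    if (standardize) {
      for (v in c("lx", "temp", "chl")) {
        mu <- mean(d[[v]]); sdv <- stats::sd(d[[v]])
        if (sdv == 0) sdv <- 1
        scaling[[v]] <- c(center = mu, scale = sdv)
        d[[v]] <- (d[[v]] - mu) / sdv
      }
    }
    X <- stats::model.matrix(~ lx * size * temp + lx * size * chl, d)
    map <- c(
      "(Intercept)" = "(Intercept)",
      "sizemedium" = "size_medium", "sizelarge" = "size_large",
      "lx" = "lx", "temp" = "temp", "chl" = "chl",
      "lx:sizemedium" = "lx:size_medium", "lx:sizelarge" = "lx:size_large",
      "sizemedium:temp" = "temp:size_medium",
      "sizelarge:temp" = "temp:size_large",
      "lx:temp" = "lx:temp",
      "sizemedium:chl" = "chl:size_medium",
      "sizelarge:chl" = "chl:size_large",
      "lx:chl" = "lx:chl",
      "lx:sizemedium:temp" = "lx:temp:size_medium",
      "lx:sizelarge:temp" = "lx:temp:size_large",
      "lx:sizemedium:chl" = "lx:chl:size_medium",
      "lx:sizelarge:chl" = "lx:chl:size_large")
    colnames(X) <- map[colnames(X)]
    X <- X[, .nightTerms, drop = FALSE]
  } else {
    if (standardize) {
      mu <- mean(d$lx); sdv <- stats::sd(d$lx)
      if (sdv == 0) sdv <- 1
      scaling[["lx"]] <- c(center = mu, scale = sdv)
      d$lx <- (d$lx - mu) / sdv
    }
    X <- stats::model.matrix(~ lx * size, d)
    map <- c("(Intercept)" = "(Intercept)", "lx" = "lx",
             "sizemedium" = "size_medium", "sizelarge" = "size_large",
             "lx:sizemedium" = "lx:size_medium",
             "lx:sizelarge" = "lx:size_large")
    colnames(X) <- map[colnames(X)]
    X <- X[, .dayNightTerms, drop = FALSE]
  }
  attr(X, "scaling") <- scaling
  X
}

#' Simulate gamma bin densities from the mixed-model design
#'
#' Draws per-row densities from the generative model behind the statistics
#' layer: a linear predictor `eta = X beta + u_date + u_profile` with
#' independent normal random intercepts, and a gamma response with shape `k`
#' and mean `exp(eta)` (variance `mean^2 / k`). Continuous covariates are
#' z-scored before entering the night design (the scaling constants are
#' attached as an attribute); the day--night design uses raw lux.
#'
#' @param designTable covariate table from [nightDesignTable()] or
#'   [dayNightDesignTable()].
#' @param beta named coefficient vector in the design's canonical term
#'   order; defaults from [nightEffectDefaults()].
#' @param sigmaDate,sigmaProfile random-intercept standard deviations.
#' @param gammaShape gamma shape parameter k (> 0).
#' @param seed integer seed.
#' @param design "night" or "daynight".
#' @return the design table with a strictly positive `density` column
#'   (ind/L); attributes "scaling" (z-score constants) and "trueEta".
#' @examples
#' tab <- nightDesignTable(nProfiles = 4)
#' sim <- simulateBinDensities(tab, nightEffectDefaults("cladoceran"),
#'                             seed = 1)
#' mean(sim$density)
#' @export
simulateBinDensities <- function(designTable,
                                 beta = nightEffectDefaults("cladoceran"),
                                 sigmaDate = 0.2, sigmaProfile = 0.14,
                                 gammaShape = 2, seed = 1L,
                                 design = c("night", "daynight")) {
  design <- match.arg(design)
  if (gammaShape <= 0) stop("gammaShape must be positive")
  X <- .designMatrix(designTable, design)
  if (length(beta) != ncol(X)) {
    stop("beta must have ", ncol(X), " entries for the ", design, " design")
  }
  date <- factor(designTable$date)
  prof <- factor(designTable$profile_id)
  eta <- .withSubstream(seed, "densities", {
    uDate <- stats::rnorm(nlevels(date), 0, sigmaDate)
    uProf <- stats::rnorm(nlevels(prof), 0, sigmaProfile)
    unname(drop(X %*% beta)) + uDate[date] + uProf[prof]
  })
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor at row ",
         which(!is.finite(eta))[1])
  }
  out <- designTable
  out$density <- .withSubstream(seed, "gamma-noise",
    stats::rgamma(length(eta), shape = gammaShape,
                  rate = gammaShape / exp(eta)))
  attr(out, "scaling") <- attr(X, "scaling")
  attr(out, "trueEta") <- eta
  out
}

#' Place individuals from bin densities
#'
#' Converts a density field into a ground-truth set of organisms: per
#' profile x bin x size-class row the count is Poisson with mean density
#' times the fully-covered bin volume (0.52 L for a 52 mm x 100 mm aperture
#' over a 10 cm bin); depths are uniform within the bin, equivalent
#' spherical diameters uniform within the taxon's size-class range, and
#' lateral offsets uniform over the frame breadth. Copepods get an elongated
#' body with antennae, cladocerans a compact ovoid.
#'
#' @param binDensities table with columns profile_id, size_class, bin_index,
#'   bin_mid_depth and density (ind/L), e.g. from [simulateBinDensities()].
#' @param taxon taxon the densities describe.
#' @param optics from [opticsConfig()].
#' @param seed integer seed.
#' @return data.frame of true individuals: profile_id, taxon, size_class,
#'   depth (m), esd_true (mm), lateral_mm, axis_ratio, antenna.
#' @export
placeIndividuals <- function(binDensities,
                             taxon = c("cladoceran", "copepod"),
                             optics = opticsConfig(), seed = 1L) {
  taxon <- match.arg(taxon)
  if (any(binDensities$density < 0)) stop("densities must be >= 0")
  ranges <- sizeClassRanges(taxon)
  .withSubstream(seed, "individuals", {
    counts <- stats::rpois(nrow(binDensities),
                           binDensities$density * optics$binVolumeL)
    idx <- rep(seq_len(nrow(binDensities)), counts)
    n <- length(idx)
    cls <- as.character(binDensities$size_class[idx])
    lo <- ranges[cls, "lo"]; hi <- ranges[cls, "hi"]
    data.frame(
      profile_id = as.character(binDensities$profile_id[idx]),
      taxon = rep(taxon, n),
      size_class = cls,
      depth = binDensities$bin_mid_depth[idx] +
        stats::runif(n, -optics$binHeight / 2, optics$binHeight / 2),
      esd_true = stats::runif(n, lo, hi),
      lateral_mm = stats::runif(n, 0, optics$frameBreadthMm),
      axis_ratio = if (taxon == "copepod") stats::runif(n, 2.2, 3.0)
                   else stats::runif(n, 1.2, 1.8),
      antenna = rep(taxon == "copepod", n))
  })
}
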