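# De-overlap, size classes, depth binning with sampled volumes, covariate
# attachment and per-profile summaries.

test_that("de-overlap strips partition the profiled span", {
  delta <- 0.03472; h <- 0.043
  tops <- (0:9) * delta
  strips <- deoverlapFrames(tops, h)
  # first strip is the full frame, later strips equal the descent
  expect_equal(strips$strip_bottom[1] - strips$strip_top[1], h)
  expect_equal(strips$strip_bottom[-1] - strips$strip_top[-1],
               rep(delta, 9), tolerance = 1e-12)
  # exact partition: no gaps, no double coverage
  expect_equal(strips$strip_top[-1], strips$strip_bottom[-10],
               tolerance = 1e-12)
  expect_equal(sum(strips$strip_bottom - strips$strip_top),
               max(tops) + h, tolerance = 1e-12)
  # random spacings no wider than the frame height still partition
  set.seed(5)
  for (i in 1:20) {
    tp <- cumsum(c(0, runif(8, 0.001, h)))
    st <- deoverlapFrames(tp, h)
    expect_true(all(st$strip_bottom - st$strip_top >= 0))
    expect_equal(st$strip_top[-1], pmax(st$strip_bottom[-9], tp[-1]),
                 tolerance = 1e-12)
    expect_equal(sum(st$strip_bottom - st$strip_top), max(tp) + h,
                 tolerance = 1e-9)
  }
  # non-overlapping frames keep their full spans
  st2 <- deoverlapFrames(c(0, 0.05, 0.10), h)
  expect_equal(st2$strip_bottom - st2$strip_top, rep(h, 3))
  expect_error(deoverlapFrames(c(0.1, 0), h), "increasing")
})

test_that("size classes use the closed published ranges with gaps", {
  expect_equal(assignSizeClass(0.72, "cladoceran"), "large")
  expect_equal(assignSizeClass(0.46, "copepod"), "medium")
  expect_equal(assignSizeClass(0.42, "cladoceran"), "unclassified")
  expect_equal(assignSizeClass(c(0.36, 0.39, 0.45, 0.53, 0.70, 0.75),
                               "cladoceran"),
               c("small", "small", "medium", "medium", "large", "large"))
  expect_equal(assignSizeClass(0.70, "copepod"), "unclassified")
  expect_error(assignSizeClass(0.5, "rotifer"), "unknown taxon")
})

test_that("binning converts counts through the sampled volume", {
  opt <- opticsConfig()
  strips <- deoverlapFrames((0:499) * opt$descentPerFrameMm / 1000, 0.043)
  det <- data.frame(profile_id = "p", frame_index = 120L,
                    depth_m = 120 * 0.03472 + 0.01, taxon = "cladoceran",
                    size_class = "large")
  bins <- binDensities(det, strips, opt)
  # 16.7 m at 10 cm: 167 bins, each with every taxon x class combination
  expect_equal(length(unique(bins$bin_index)), 167)
  expect_equal(nrow(bins), 167 * 6)
  # a single detection in a fully covered bin: 1 / 0.52 L
  hit <- bins[bins$count == 1, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$density, 1 / 0.52, tolerance = 1e-9)
  # conservation: densities times volumes reproduce integer counts
  expect_equal(sum(bins$density * bins$sampled_volume_L), 1,
               tolerance = 1e-9)
  expect_true(all(abs(bins$density * bins$sampled_volume_L -
                        round(bins$density * bins$sampled_volume_L)) <
                    1e-9))
  # empty input: all densities zero
  bins0 <- binDensities(det[0, ], strips, opt)
  expect_true(all(bins0$density == 0))
})

test_that("binned densities equal a brute-force recount", {
  opt <- opticsConfig()
  set.seed(17)
  for (rep in 1:10) {
    nf <- 80
    strips <- deoverlapFrames((0:(nf - 1)) * opt$descentPerFrameMm / 1000,
                              0.043)
    n <- rpois(1, 40) + 1
    det <- data.frame(
      profile_id = "p",
      frame_index = sample(0:(nf - 1), n, replace = TRUE),
      taxon = sample(c("cladoceran", "copepod", "other"), n, TRUE),
      esd_mm = runif(n, 0.36, 0.80))
    det$depth_m <- runif(n, det$frame_index * 0.03472,
                         det$frame_index * 0.03472 + 0.043)
    bins <- binDensities(det, strips, opt)
    # brute force: count retained individuals per bin x taxon x class
    m <- match(det$frame_index, strips$frame_index)
    keep <- det$depth_m >= strips$strip_top[m] &
      det$depth_m < strips$strip_bottom[m] & det$taxon != "other"
    kd <- det[keep, ]
    kd$size_class <- assignSizeClass(kd$esd_mm, kd$taxon)
    kd <- kd[kd$size_class != "unclassified", ]
    for (j in which(bins$count > 0)) {
      manual <- sum(kd$taxon == bins$taxon[j] &
                      kd$size_class == as.character(bins$size_class[j]) &
                      floor(kd$depth_m / 0.1) == bins$bin_index[j])
      expect_equal(bins$count[j], manual)
    }
    expect_equal(sum(bins$count), nrow(kd))
    expect_equal(sum(bins$density * bins$sampled_volume_L), nrow(kd),
                 tolerance = 1e-9)
  }
})

test_that("covariate attachment joins light and interpolates environment", {
  opt <- opticsConfig()
  strips <- deoverlapFrames((0:480) * opt$descentPerFrameMm / 1000, 0.043)
  bins <- binDensities(data.frame(profile_id = character(),
                                  frame_index = integer(),
                                  depth_m = numeric(), taxon = character(),
                                  size_class = character()),
                       strips, opt)
  env <- makeEnvironment(noiseSd = 0)
  light <- attenuateProfile(0.06, 0.5)
  out <- attachCovariates(bins, env, light)
  expect_equal(nrow(out), nrow(bins))
  expect_false(anyNA(out$temperature_C))
  # floored light bins enter the table as exact zeros
  expect_true(any(out$illuminance_lx == 0))
  expect_true(all(out$illuminance_lx ==
                    illuminance(light)[out$bin_index + 1]))
  # a midpoint on a sonde node takes the node value (0.05 m off nodes
  # interpolates; check a representative interior bin against closed form)
  i <- which(out$bin_index == 49)[1]  # midpoint 4.95 m
  tA <- environmentAt(env, 4.5)$temperature
  tB <- environmentAt(env, 5.0)$temperature
  expect_equal(out$temperature_C[i], tA + 0.9 * (tB - tA),
               tolerance = 1e-9)
  shallow <- makeEnvironment(depthGrid = seq(0, 10, 0.5), noiseSd = 0)
  expect_error(attachCovariates(bins, shallow, light), "span")
})

test_that("profile mean depths use individual detections", {
  det <- data.frame(profile_id = "p1", taxon = "cladoceran",
                    depth_m = c(1, 2, 3))
  s <- profileMeanDepth(det)
  expect_equal(s$mean_depth, 2.0)
  expect_equal(s$se_depth, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(s$n, 3)
  # adding a detection at the mean leaves the mean unchanged
  s2 <- profileMeanDepth(rbind(det, data.frame(profile_id = "p1",
                                               taxon = "cladoceran",
                                               depth_m = 2)))
  expect_equal(s2$mean_depth, 2.0)
  # single detection: SE defined as zero
  s3 <- profileMeanDepth(data.frame(profile_id = "p2", taxon = "copepod",
                                    depth_m = 5))
  expect_equal(s3$se_depth, 0)
  expect_equal(nrow(profileMeanDepth(det[0, ])), 0)
})
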