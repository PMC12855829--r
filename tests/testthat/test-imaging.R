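# Flat-fielding, binarization/labelling, ROI extraction, morphometry and
# the rule-based classifier.

test_that("flat-fielding removes illumination structure", {
  # uniform frame with uniform reference stays uniform
  u <- matrix(200, 40, 50)
  expect_true(all(flatField(u, matrix(100, 40, 50)) == 200))
  # a 20% linear gradient corrects to background CV below 1%
  grad <- illuminationField(60, 80, gradient = 0.2)
  frame <- 220 * grad
  ref <- backgroundReference(list(frame, frame, frame))
  corr <- flatField(frame, ref)
  expect_lt(stats::sd(corr) / mean(corr), 0.01)
  # near-idempotence: a second pass against a flat reference moves pixels
  # by under 0.5%
  corr2 <- flatField(corr, matrix(mean(corr), nrow(corr), ncol(corr)))
  expect_lt(max(abs(corr2 - corr) / corr), 0.005)
  expect_error(flatField(u, matrix(0, 40, 50)), "zeros")
})

test_that("background reference is the per-pixel median over frames", {
  set.seed(9)
  mats <- lapply(1:7, function(i) matrix(rnorm(30, 100, 10), 5, 6))
  ref <- backgroundReference(mats, index = 4, window = 7)
  arr <- array(unlist(mats), dim = c(5, 6, 7))
  expect_equal(ref, apply(arr, c(1, 2), stats::median), tolerance = 1e-12)
})

test_that("binarization labels dark particles with 8-connectivity", {
  # blank noise-free frame: no components
  expect_equal(max(binarizeSegment(matrix(200, 30, 30))), 0)
  # one disc of radius 20 px: one component with the analytic disc area
  img <- matrix(230, 120, 120)
  rc <- expand.grid(r = 1:120, c = 1:120)
  inside <- (rc$r - 60)^2 + (rc$c - 60)^2 <= 20^2
  img[cbind(rc$r[inside], rc$c[inside])] <- 40
  set.seed(2)
  img <- img + matrix(rnorm(120 * 120, 0, 2), 120, 120)
  lab <- binarizeSegment(img)
  # noise may add isolated specks -- those are removed downstream by the
  # ROI size thresholds; here only real (>= 20 px) components count
  realComps <- function(lab) which(tabulate(lab[lab > 0]) >= 20)
  expect_length(realComps(lab), 1)
  area <- sum(lab == realComps(lab)[1])
  expect_lt(abs(area - pi * 20^2) / (pi * 20^2), 0.1)
  # two discs separated by more than 2 px of background stay distinct
  img2 <- matrix(230, 60, 60)
  img2[20:26, 10:16] <- 40
  img2[20:26, 20:26] <- 40
  expect_length(realComps(binarizeSegment(img2 +
    matrix(rnorm(3600, 0, 1.5), 60, 60))), 2)
  # diagonal contact merges into one component (8-connectivity)
  img3 <- matrix(230, 40, 40)
  img3[10:14, 10:14] <- 40
  img3[15:19, 15:19] <- 40
  expect_length(realComps(binarizeSegment(img3 +
    matrix(rnorm(1600, 0, 1.5), 40, 40))), 1)
})

test_that("ROI extraction applies the size thresholds", {
  lab <- matrix(0L, 50, 50)
  lab[2:4, 2:4] <- 1L              # 9 px, below threshold
  lab[20:35, 20:35] <- 2L          # 256 px, retained
  img <- matrix(200, 50, 50)
  rois <- extractRois(lab, img, minPx = 50, maxPx = 5e5, marginPx = 3)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$area, 256)
  # a 230 px component (smallest admissible organism) survives
  lab2 <- matrix(0L, 40, 40)
  lab2[which(outer((1:40 - 20)^2, (1:40 - 20)^2, "+") <= 8.5^2)] <- 1L
  expect_length(extractRois(lab2, matrix(200, 40, 40), 50, 5e5), 1)
  expect_gte(sum(lab2 == 1), 220)
  # never more vignettes than components
  expect_lte(length(rois), 2)
  expect_error(extractRois(lab, img, minPx = 10, maxPx = 5), "below maxPx")
})

test_that("morphometry recovers ellipse axes and the prolate-spheroid ESD", {
  pitch <- 0.021
  # 1.0 mm x 0.5 mm ellipse: ESD = (1.0 * 0.25)^(1/3) = 0.63 mm
  v <- ellipseVignette(a = 0.5 / pitch, b = 0.25 / pitch)
  m <- measureRoi(v, pitch)
  expect_equal(m$major_axis_mm, 1.0, tolerance = 0.03)
  expect_equal(m$minor_axis_mm, 0.5, tolerance = 0.03)
  expect_equal(m$esd_mm, (1.0 * 0.5^2)^(1 / 3), tolerance = 0.03)
  # a circle's ESD is its diameter
  d <- discVignette(r = 15)
  md <- measureRoi(d, pitch)
  expect_equal(md$esd_mm, 30 * pitch, tolerance = 0.03)
  expect_equal(md$aspect, 1, tolerance = 0.05)
  # pixel area converts at pitch^2
  expect_equal(md$area_px * pitch^2,
               sum(d$mask) * 0.021^2, tolerance = 1e-12)
  expect_true(m$minor_axis_mm <= m$major_axis_mm)
  expect_error(measureRoi(list(mask = matrix(FALSE, 3, 3))), "empty")
})

test_that("rule-based classifier separates the rendered classes", {
  mk <- function(aspect, solidity, protrusions = 0) {
    list(aspect = aspect, solidity = solidity, protrusions = protrusions)
  }
  expect_equal(classifyRoi(mk(2.5, 0.8, 2))$taxon, "copepod")
  expect_equal(classifyRoi(mk(1.8, 0.7, 2))$taxon, "copepod")  # antennae
  expect_equal(classifyRoi(mk(1.5, 0.95))$taxon, "cladoceran")
  expect_equal(classifyRoi(mk(1.5, 0.7))$taxon, "other")
  # scores stay in [0, 1] over a parameter grid
  for (a in seq(1, 4, by = 0.5)) {
    for (s in seq(0.5, 1, by = 0.1)) {
      sc <- classifyRoi(mk(a, s, a > 2))$score
      expect_true(sc >= 0 && sc <= 1)
    }
  }
})

test_that("admissibility filter keeps strictly above 0.36 mm", {
  det <- data.frame(esd_mm = c(0.30, 0.36, 0.37, 0.72), id = 1:4)
  kept <- filterDetections(det)
  expect_equal(kept$id, 3:4)
  # subset of input, order preserved, idempotent
  expect_true(all(kept$id %in% det$id))
  expect_identical(filterDetections(kept), kept)
  expect_equal(nrow(filterDetections(det[0, ])), 0)
})
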