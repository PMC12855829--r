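# Shared fixtures, built once per test run. Kept deliberately small: a
# short water column and few profiles are enough to exercise every code
# path; the full study dimensions are exercised in the acceptance tests.

.fx <- new.env()

tinyNightTable <- function() {
  if (is.null(.fx$night)) {
    .fx$night <- nightDesignTable(nProfiles = 6, lakeDepth = 5, seed = 1L)
  }
  .fx$night
}

# single rendered frame with a known cladoceran and copepod, full resolution
renderedPairFrame <- function() {
  if (is.null(.fx$pair)) {
    opt <- opticsConfig(1L)
    ind <- data.frame(
      profile_id = "fx", taxon = c("cladoceran", "copepod"),
      size_class = c("large", "medium"), depth = c(0.010, 0.030),
      esd_true = c(0.72, 0.46), lateral_mm = c(15, 35),
      axis_ratio = c(1.5, 2.6), antenna = c(FALSE, TRUE))
    .fx$pairInd <- ind
    .fx$pair <- renderProfileFrames(ind, opt, maxDepth = 0.0431,
                                    noiseSd = 0, seed = 7)[[1]]
  }
  list(frame = .fx$pair, truth = .fx$pairInd)
}

# deterministic binary disc mask vignette of radius r pixels
discVignette <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  mask <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
  list(mask = mask, pixels = NULL, offset = c(row = 1, col = 1),
       area = sum(mask))
}

# axis-aligned binary ellipse mask (semi-axes a >= b, in pixels)
ellipseVignette <- function(a, b, pad = 4) {
  nr <- 2 * (ceiling(b) + pad) + 1
  nc <- 2 * (ceiling(a) + pad) + 1
  cr <- ceiling(b) + pad + 1
  cc <- ceiling(a) + pad + 1
  mask <- outer(seq_len(nr), seq_len(nc),
                function(i, j) ((j - cc) / a)^2 + ((i - cr) / b)^2 <= 1)
  list(mask = mask, pixels = NULL, offset = c(row = 1, col = 1),
       area = sum(mask))
}
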