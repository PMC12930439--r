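# Band arithmetic, core spectra and morphotype ratios.

test_that("nearest-band lookup hits the readout wavelengths of the default grid", {
  g <- bandGrid()
  expect_identical(bandIndex(g, 502), 4L)
  expect_identical(bandIndex(g, 545), 8L)
  expect_identical(bandIndex(g, 588), 12L)
  expect_equal(bandCenters(g)[bandIndex(g, 502)], 502.1)
  expect_equal(bandCenters(g)[bandIndex(g, 545)], 544.9)
  expect_equal(bandCenters(g)[bandIndex(g, 588)], 587.7)
  expect_error(bandIndex(g, 300), "outside grid span")
  expect_error(bandIndex(g, 800), "outside grid span")
})

test_that("basis spectra satisfy their peak-position and normalization invariants", {
  g <- bandGrid()
  b <- makeBasisSpectra(g)
  expect_true(all(b@compact >= 0) && all(b@filamentous >= 0))
  expect_equal(max(b@compact), 1)
  expect_equal(max(b@filamentous), 1)
  expect_identical(which.max(b@compact), bandIndex(g, 502))
  # filamentous: value 1.0 exactly at the 588-nearest band (global max)
  expect_equal(b@filamentous[bandIndex(g, 588)], 1)
  # its two largest local maxima sit at the 545- and 588-nearest bands
  v <- b@filamentous
  locmax <- which(diff(sign(diff(v))) == -2) + 1L
  ends <- c(if (v[1] > v[2]) 1L, if (v[length(v)] > v[length(v) - 1]) length(v))
  locmax <- sort(c(locmax, ends))
  top2 <- locmax[order(-v[locmax])][1:2]
  expect_setequal(top2, c(bandIndex(g, 545), bandIndex(g, 588)))
  expect_error(makeBasisSpectra(bandGrid(470, 10.7, 3)), "invalid grid")
})

test_that("compact basis is 502/588-dominant relative to the filamentous basis", {
  g <- bandGrid()
  b <- makeBasisSpectra(g)
  rc <- ratio502to588(emissionSpectrum(b@compact, g))
  rf <- ratio502to588(emissionSpectrum(b@filamentous, g))
  expect_gt(rc, 1)
  expect_lt(rf, 1)
  expect_gt(rc, rf)
})

test_that("plaque core spectrum equals the brute-force per-pixel oracle", {
  g <- bandGrid(500, 10, 6L)
  for (s in 1:5) {
    set.seed(s)
    arr <- array(runif(12 * 12 * 6, 0.1, 1), c(12, 12, 6))
    stack <- new("SpectralStack", data = arr, grid = g, pixel_size_um = 0.5)
    rois <- lapply(1:3, function(i) sample(144, 10))
    got <- plaqueCoreSpectrum(stack, rois)
    # independent oracle: loop per pixel and band
    per_roi <- sapply(rois, function(px) {
      sapply(1:6, function(b) {
        vals <- numeric(length(px))
        for (i in seq_along(px)) {
          r <- (px[i] - 1) %% 12 + 1
          cc <- (px[i] - 1) %/% 12 + 1
          vals[i] <- arr[r, cc, b]
        }
        mean(vals)
      })
    })
    expected <- rowMeans(per_roi)
    expected <- expected / max(expected)
    expect_equal(got@intensities, expected, tolerance = 1e-9)
    expect_true(got@normalized)
    expect_equal(max(got@intensities), 1)
  }
})

test_that("core spectrum handles constant ROIs and rejects degenerate input", {
  g <- bandGrid(500, 10, 4L)
  spec <- c(2, 4, 8, 4)
  arr <- array(rep(spec, each = 25), c(5, 5, 4))
  stack <- new("SpectralStack", data = arr, grid = g, pixel_size_um = 0.5)
  rois <- list(1:5, 6:10, 11:15)
  got <- plaqueCoreSpectrum(stack, rois)
  expect_equal(got@intensities, spec / max(spec))
  zero <- new("SpectralStack", data = array(0, c(5, 5, 4)), grid = g,
              pixel_size_um = 0.5)
  expect_error(plaqueCoreSpectrum(zero, rois), "degenerate-spectrum")
  expect_error(plaqueCoreSpectrum(stack, list(1:3, integer(0), 4:6)),
               "empty-region")
  expect_error(plaqueCoreSpectrum(stack, list(1:3, 4:6)), "exactly 3")
})

test_that("spectral ratios are unity for equal peaks, scale-invariant, and guarded", {
  g <- bandGrid()
  flat <- emissionSpectrum(rep(1, 22), g)
  expect_equal(ratio502to588(flat), 1)
  expect_equal(ratio545to588(flat), 1)
  set.seed(3)
  raw <- runif(22, 0.2, 1)
  r1 <- ratio502to588(emissionSpectrum(raw, g))
  r2 <- ratio502to588(emissionSpectrum(7.3 * raw, g))
  expect_equal(r1, r2)
  bad <- rep(1, 22); bad[bandIndex(g, 588)] <- 0
  expect_error(ratio502to588(emissionSpectrum(bad, g, normalize = FALSE)),
               "undefined-ratio")
})

test_that("ratio statistics are invariant to positive scaling of the raw stack", {
  tr <- makePlaqueTruth(area_um2 = 400, compaction_f = 0.6)
  tile <- renderPlaque(tr, makeBasisSpectra(), noise_sd = 0)
  core <- getChannel(tile, "qftaa") > 0.05
  rois <- coreROIs(core)
  r1 <- ratio502to588(plaqueCoreSpectrum(tile@stack, rois))
  scaled <- new("SpectralStack", data = tile@stack@data * 4.2,
                grid = tile@stack@grid, pixel_size_um = 0.5)
  expect_equal(ratio502to588(plaqueCoreSpectrum(scaled, rois)), r1)
})

test_that("animal mean ratio averages and flags small plaque counts", {
  r <- animalMeanRatio(c(1, 1, 1), min_plaques = 3)
  expect_equal(r$mean, 1)
  expect_false(r$below_minimum)
  r <- animalMeanRatio(runif(10), min_plaques = 35)
  expect_true(r$below_minimum)
  expect_equal(animalMeanRatio(c(0.5, 1.5), min_plaques = 2)$mean, 1)
  expect_error(animalMeanRatio(numeric(0)), "empty-input")
})

test_that("core ROI placement yields three in-core ROIs deterministically", {
  tr <- makePlaqueTruth(area_um2 = 900, core_fraction = 0.3)
  tile <- renderPlaque(tr, makeBasisSpectra(), include_stack = FALSE)
  core <- getChannel(tile, "qftaa") > 0.05
  rois <- coreROIs(core)
  expect_length(rois, 3)
  expect_true(all(lengths(rois) > 0))
  expect_true(all(unlist(rois) %in% which(core)))
  expect_identical(rois, coreROIs(core))
  # tiny cores still give three (possibly single-pixel) ROIs
  small <- matrix(FALSE, 9, 9); small[4:5, 4:5] <- TRUE
  rois2 <- coreROIs(small)
  expect_length(rois2, 3)
  expect_true(all(unlist(rois2) %in% which(small)))
  expect_error(coreROIs(matrix(FALSE, 4, 4)), "empty-region")
})
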