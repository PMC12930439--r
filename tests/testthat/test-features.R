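# Per-plaque feature extraction, colocalization and overlap curves.

test_that("colocalization equals the exhaustive pixel-intersection oracle", {
  set.seed(17)
  for (i in 1:100) {
    a <- randomMask(c(20, 20), runif(1, 0.1, 0.9))
    b <- randomMask(c(20, 20), runif(1, 0.1, 0.9))
    if (!any(b)) b[1, 1] <- TRUE
    # oracle: explicit set intersection over pixel coordinate pairs
    setA <- which(a); setB <- which(b)
    oracle <- 100 * length(intersect(setA, setB)) / length(setB)
    expect_identical(colocalizationFraction(a, b), oracle)
  }
  m <- randomMask(c(10, 10), 0.5); m[1, 1] <- TRUE
  expect_equal(colocalizationFraction(m, m), 100)
  expect_equal(colocalizationFraction(!m, m), 0)
  expect_error(colocalizationFraction(m, matrix(FALSE, 10, 10)),
               "empty-region")
  expect_error(colocalizationFraction(m, matrix(TRUE, 5, 5)), "shape error")
})

test_that("area and intensity ratios follow their definitions", {
  expect_equal(lcoAreaRatio(data.frame(qftaa_area_um2 = 50,
                                       hftaa_area_um2 = 50)), 1)
  expect_equal(lcoAreaRatio(0, 120), 0)
  expect_error(lcoAreaRatio(10, 0), "undefined-ratio")
  img <- matrix(runif(100), 10)
  core <- randomMask(c(10, 10), 0.5); core[2, 2] <- TRUE
  expect_equal(coreIntensityRatio(img, img, core), 1)
  expect_equal(coreIntensityRatio(2 * img, img, core), 2)
  expect_error(coreIntensityRatio(img, img, matrix(FALSE, 10, 10)),
               "empty-region")
  expect_error(coreIntensityRatio(img, 0 * img, core), "undefined-ratio")
})

test_that("extraction reproduces planted areas exactly on noise-free scenes", {
  sim <- simulateCohort(cohortConfig(n_animals = 3, plaques_per_animal = 5,
                                     noise_sd = 0), seed = 8,
                        render = "channels")
  planted <- cohortFeatures(sim$truth)
  got <- do.call(rbind, lapply(sim$scenes, function(sc) {
    labs <- gatePlaques(segmentPlaques(getChannel(sc, "hftaa"), 0.5,
                                       min_area_um2 = 30,
                                       pixel_size_um = 0.5), 100, 2500)
    extractFeatures(sc, labs, defaultThresholds, metadata = sim$metadata)
  }))
  m <- merge(got, planted, by = "plaque_id", suffixes = c(".img", ".true"))
  expect_equal(nrow(m), nrow(planted))
  for (col in c("plaque_area_um2", "qftaa_area_um2", "hftaa_area_um2",
                "iba1_area_um2", "app_area_um2")) {
    expect_equal(m[[paste0(col, ".img")]], m[[paste0(col, ".true")]],
                 tolerance = 1e-12)
  }
  expect_equal(m$core_intensity_ratio_qf_hf.img,
               m$core_intensity_ratio_qf_hf.true, tolerance = 1e-4)
  expect_equal(m$area_ratio_qf_hf.img, m$area_ratio_qf_hf.true,
               tolerance = 1e-12)
  expect_true(all(m$group.img == m$group.true))
})

test_that("blank and half-covering co-stains yield normalized areas 0 and 0.5", {
  tr <- makePlaqueTruth(area_um2 = 400, core_fraction = 0.25,
                        compaction_f = 0.8, iba1_area_um2 = 0,
                        app_area_um2 = 200)
  tile <- renderPlaque(tr, makeBasisSpectra(), include_stack = FALSE)
  labs <- gatePlaques(segmentPlaques(getChannel(tile, "hftaa"), 0.5,
                                     min_area_um2 = 30,
                                     pixel_size_um = 0.5), 100, 2500)
  fe <- extractFeatures(tile, labs, defaultThresholds)
  expect_equal(fe$iba1_area_norm, 0)          # blank channel
  expect_equal(fe$app_area_norm, 0.5)         # planted half of plaque area
  expect_error(extractFeatures(tile, labs, c(qftaa = 0.05, hftaa = 0.5,
                                             gfap = 0.5)),
               "missing channel")
  expect_error(extractFeatures(tile, labs, c(hftaa = 0.5)),
               "missing-channel")
})

test_that("feature records are invariant to whole-scene translation", {
  tr <- makePlaqueTruth(area_um2 = 400, core_fraction = 0.25,
                        compaction_f = 0.7, app_area_um2 = 120)
  tile <- renderPlaque(tr, makeBasisSpectra(), include_stack = FALSE)
  d <- dim(tile@channels$hftaa)
  shift <- function(img, dr, dc) {
    out <- matrix(0, d[1] + 10, d[2] + 10)
    out[dr + seq_len(d[1]), dc + seq_len(d[2])] <- img
    out
  }
  trans <- methods::new("SyntheticScene",
    stack = NULL,
    channels = c(lapply(tile@channels[setdiff(names(tile@channels),
                                              "congo_rgb")],
                        shift, dr = 3, dc = 7),
                 list(congo_rgb = {
                   a <- array(0.5, c(d[1] + 10, d[2] + 10, 3))
                   for (k in 1:3) a[, , k] <- shift(tile@channels$congo_rgb[, , k],
                                                    3, 7)
                   a
                 })),
    pixel_size_um = 0.5, truth = data.frame(), scene_id = "t")
  fe0 <- extractFeatures(tile, gatePlaques(
    segmentPlaques(getChannel(tile, "hftaa"), 0.5, 30, pixel_size_um = 0.5),
    100, 2500), defaultThresholds)
  fe1 <- extractFeatures(trans, gatePlaques(
    segmentPlaques(getChannel(trans, "hftaa"), 0.5, 30, pixel_size_um = 0.5),
    100, 2500), defaultThresholds)
  common <- intersect(names(fe0), names(fe1))
  common <- common[vapply(fe0[common], is.numeric, logical(1))]
  expect_equal(fe1[common], fe0[common], tolerance = 1e-12)
})

test_that("overlap-by-size curves aggregate per-bin means correctly", {
  # identical mask pairs: flat curve at 100 regardless of bin
  pairs <- lapply(c(120, 400, 900, 1600), function(a) {
    m <- rectImage(a)$masks[[1]]
    list(first = m, second = m)
  })
  curve <- overlapBySize(pairs, bin_edges = c(100, 500, 2000))
  expect_true(all(curve$mean_overlap[curve$n > 0] == 100))
  # single bin reduces to the grand mean
  set.seed(5)
  pairs2 <- lapply(1:6, function(i) {
    s <- randomMask(c(15, 15), 0.5); s[1, 1] <- TRUE
    list(first = randomMask(c(15, 15), 0.4), second = s)
  })
  ovl <- sapply(pairs2, function(p) colocalizationFraction(p$first, p$second))
  single <- overlapBySize(pairs2, bin_edges = c(0, 1e6))
  expect_equal(single$mean_overlap, mean(ovl))
  expect_error(overlapBySize(pairs2, bin_edges = c(10, 5)), "parameter error")
})

test_that("planted size-dependent overlap yields a monotone curve", {
  # plant overlap rising linearly with plaque size and recover the trend
  sizes <- c(150, 150, 600, 600, 1800, 1800)
  fracs <- sizes / 2000
  pairs <- mapply(function(a, fr) {
    m <- rectImage(a)$masks[[1]]
    px <- which(m)
    f <- m & FALSE
    f[px[seq_len(round(fr * length(px)))]] <- TRUE
    list(first = f, second = m)
  }, sizes, fracs, SIMPLIFY = FALSE)
  curve <- overlapBySize(pairs, bin_edges = c(100, 300, 1000, 2500))
  expect_equal(curve$n, c(2, 2, 2))
  expect_true(all(diff(curve$mean_overlap) > 0))
  expect_equal(curve$mean_overlap, 100 * c(150, 600, 1800) / 2000,
               tolerance = 0.02)
})
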