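# Scene generator: spectra, costains, cohort structure, planted R^2.

test_that("noise-free core spectra follow the compaction mixture exactly", {
  b <- makeBasisSpectra()
  q16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535
  tr1 <- makePlaqueTruth(area_um2 = 400, core_fraction = 0.25, compaction_f = 1)
  tile <- renderPlaque(tr1, b, noise_sd = 0)
  core_px <- which(getChannel(tile, "qftaa") > 0.5)
  expected <- q16(0.8 * b@compact)
  for (px in core_px[c(1, length(core_px) %/% 2, length(core_px))]) {
    got <- sapply(1:22, function(k) tile@stack@data[
      (px - 1) %% nrow(tile@stack@data[, , 1]) + 1,
      (px - 1) %/% nrow(tile@stack@data[, , 1]) + 1, k])
    expect_identical(got, expected)
  }
  # f = 0: core and corona spectra identical (both pure filamentous)
  tr0 <- makePlaqueTruth(area_um2 = 400, core_fraction = 0.25, compaction_f = 0)
  t0 <- renderPlaque(tr0, b, noise_sd = 0)
  plq <- getChannel(t0, "hftaa") > 0.5
  expect_true(all(vapply(seq_len(22), function(k)
    length(unique(t0@stack@data[, , k][plq])) == 1, logical(1))))
})

test_that("identical seeds give bit-identical tiles; invalid parameters error", {
  b <- makeBasisSpectra()
  tr <- makePlaqueTruth(area_um2 = 300, compaction_f = 0.5)
  t1 <- renderPlaque(tr, b, noise_sd = 0.05, rng_seed = 42L)
  t2 <- renderPlaque(tr, b, noise_sd = 0.05, rng_seed = 42L)
  expect_identical(t1@stack@data, t2@stack@data)
  expect_identical(t1@channels, t2@channels)
  t3 <- renderPlaque(tr, b, noise_sd = 0.05, rng_seed = 43L)
  expect_false(identical(t1@channels$qftaa, t3@channels$qftaa))
  expect_error(renderPlaque(tr, b, noise_sd = -1), ">= 0")
  expect_error(makePlaqueTruth(compaction_f = 1.2), "\\[0, 1\\]")
})

test_that("dystrophy channel area equals the planted linear predictor", {
  # beta = (1, 0, 0), no noise: thresholded APP area == corona area exactly
  tr <- makePlaqueTruth(area_um2 = 900, core_fraction = 0.2,
                        compaction_f = 0.7, app_area_um2 = NA)
  ch <- renderCostains(tr, beta = c(h = 1, i = 0, q = 0), noise_sigma = 0)
  expect_equal(sum(ch$app > 0.5) * 0.25, tr$corona_area_um2)
  # zero coefficients: no dystrophy at all
  ch0 <- renderCostains(tr, beta = c(h = 0, i = 0, q = 0), noise_sigma = 0)
  expect_equal(sum(ch0$app > 0.5), 0)
  # Congo Red mask is confined to the core
  core <- ch$qftaa > 0.05
  expect_true(all(congoRedMask(ch$congo_rgb)[!core] == FALSE))
  expect_true(all(congoRedMask(ch$congo_rgb) == core))
  expect_error(renderCostains(tr, beta = c(h = 1, i = NA, q = 0)), "finite")
  expect_error(renderCostains(tr, beta = c(h = 1, i = 0, q = 0),
                              noise_sigma = -1), ">= 0")
})

test_that("rendered dystrophy areas match planted predictor within one pixel across a cohort", {
  sim <- simulateCohort(cohortConfig(n_animals = 2, plaques_per_animal = 5,
                                     noise_sd = 0, target_r2 = NULL,
                                     noise_sigma = 0),
                        seed = 9, render = "channels")
  pa <- 0.25
  for (sc in sim$scenes) {
    labs <- gatePlaques(segmentPlaques(getChannel(sc, "hftaa"), 0.5,
                                       min_area_um2 = 30,
                                       pixel_size_um = 0.5), 100, 2500)
    fe <- extractFeatures(sc, labs, defaultThresholds)
    tru <- sim$truth@plaques[match(fe$plaque_id, sim$truth@plaques$plaque_id), ]
    expect_true(all(abs(fe$app_area_um2 - tru$eta_um2) <= pa))
  }
})

test_that("cohorts have the configured shape, conservation and reproducibility", {
  cfg <- cohortConfig(n_animals = 10, plaques_per_animal = 20)
  s1 <- simulateCohort(cfg, seed = 4)
  s2 <- simulateCohort(cfg, seed = 4)
  plq <- plaqueTruth(s1$truth)
  expect_equal(nrow(plq), 200)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(plq, plaqueTruth(s2$truth))
  # conservation: per-animal counts sum to the total
  expect_equal(sum(table(plq$animal_id)), nrow(plq))
  expect_true(all(table(plq$animal_id) == 20))
  s3 <- simulateCohort(cfg, seed = 5)
  expect_false(identical(plq$compaction_f,
                         plaqueTruth(s3$truth)$compaction_f))
  expect_error(simulateCohort(cohortConfig(n_animals = 1)), "empty design")
  expect_error(simulateCohort(cfg, seed = NULL), "seed")
})

test_that("LPS-group compaction shift lowers planted compaction versus control", {
  sim <- simulateCohort(cohortConfig(n_animals = 12, plaques_per_animal = 30),
                        seed = 21)
  d <- merge(plaqueTruth(sim$truth), sim$metadata)
  means <- tapply(d$compaction_f, d$group, mean)
  expect_lt(means[["4xLPS"]], means[["PBS"]])
  expect_lt(means[["1xLPS"]], means[["PBS"]])
})

test_that("mean core 502/588 ratio is strictly increasing in compaction", {
  b <- makeBasisSpectra()
  ratios <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    tr <- makePlaqueTruth(area_um2 = 400, core_fraction = 0.25,
                          compaction_f = f)
    tile <- renderPlaque(tr, b, noise_sd = 0)
    core <- matrix(FALSE, dim(tile@channels$hftaa)[1],
                   dim(tile@channels$hftaa)[2])
    core[plaqueMorph:::.discPixels(dim(core), (dim(core) + 1) / 2,
                                   round(tr$core_area_um2 / 0.25))] <- TRUE
    ratio502to588(plaqueCoreSpectrum(tile@stack, coreROIs(core)))
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("planted R^2 matches its definition and the calibration target", {
  s0 <- simulateCohort(cohortConfig(n_animals = 3, plaques_per_animal = 5,
                                    target_r2 = NULL, noise_sigma = 0),
                       seed = 2)
  expect_equal(plantedR2(s0$truth), 1)
  sz <- simulateCohort(cohortConfig(n_animals = 3, plaques_per_animal = 5,
                                    beta_h = 0, beta_i = 0, beta_q = 0,
                                    target_r2 = NULL, noise_sigma = 50),
                       seed = 2)
  expect_equal(plantedR2(sz$truth), 0)
  s6 <- simulateCohort(cohortConfig(n_animals = 20, plaques_per_animal = 100,
                                    target_r2 = 0.60), seed = 2)
  expect_equal(plantedR2(s6$truth), 0.60, tolerance = 0.02)
  # degenerate: all-zero coefficients and zero noise is undefined
  szz <- simulateCohort(cohortConfig(n_animals = 3, plaques_per_animal = 5,
                                     beta_h = 0, beta_i = 0, beta_q = 0,
                                     target_r2 = NULL, noise_sigma = 0),
                        seed = 2)
  expect_error(plantedR2(szz$truth), "zero total variance")
})
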