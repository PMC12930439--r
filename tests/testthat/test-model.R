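# Dystrophy SVR, grouped validation, importance, leverage OLS.

test_that("animal-level splits keep groups disjoint and reproducible", {
  feat <- cohortFeatures(simulateCohort(
    cohortConfig(n_animals = 10, plaques_per_animal = 4), seed = 1)$truth)
  sp <- splitByAnimal(feat, train_fraction = 0.8, seed = 2)
  expect_length(sp$train_groups, 8)
  expect_length(sp$test_groups, 2)
  expect_length(intersect(sp$train_groups, sp$test_groups), 0)
  expect_true(all(sp$train$animal_id %in% sp$train_groups))
  sp2 <- splitByAnimal(feat, train_fraction = 0.8, seed = 2)
  expect_identical(sp$train_groups, sp2$train_groups)
  one <- feat[feat$animal_id == "a01", ]
  expect_error(splitByAnimal(one), "insufficient-groups")
})

test_that("SVR recovers a noiseless planted signal almost perfectly", {
  sim <- simulateCohort(cohortConfig(n_animals = 12, plaques_per_animal = 30,
                                     beta_h = 1, beta_i = 0, beta_q = 0,
                                     target_r2 = NULL, noise_sigma = 0),
                        seed = 6)
  feat <- cohortFeatures(sim$truth)
  sp <- splitByAnimal(feat, seed = 6)
  m <- fitSVR(sp$train, seed = 6)
  expect_gte(evaluateR2(m, sp$test), 0.99)
})

test_that("hyperparameter selection and predictions are seed-deterministic", {
  feat <- cohortFeatures(simulateCohort(
    cohortConfig(n_animals = 8, plaques_per_animal = 15), seed = 3)$truth)
  sp <- splitByAnimal(feat, seed = 1)
  m1 <- fitSVR(sp$train, cost_grid = c(1, 10), gamma_grid = c(0.3, 1), seed = 5)
  m2 <- fitSVR(sp$train, cost_grid = c(1, 10), gamma_grid = c(0.3, 1), seed = 5)
  expect_identical(m1@best_params[c("cost", "gamma")],
                   m2@best_params[c("cost", "gamma")])
  expect_identical(predictModel(m1, sp$test), predictModel(m2, sp$test))
})

test_that("constant responses and degenerate tests are handled gracefully", {
  feat <- cohortFeatures(simulateCohort(
    cohortConfig(n_animals = 6, plaques_per_animal = 10), seed = 4)$truth)
  feat$app_area_um2 <- 100
  sp <- splitByAnimal(feat, seed = 1)
  m <- fitSVR(sp$train, cv_folds = 4, cost_grid = 1, gamma_grid = 1, seed = 1)
  expect_equal(predictModel(m, sp$test), rep(100, nrow(sp$test)),
               tolerance = 0.2)
  expect_error(evaluateR2(m, sp$test), "undefined-R\\^2")
})

test_that("standardization statistics come from training rows only", {
  feat <- cohortFeatures(simulateCohort(
    cohortConfig(n_animals = 8, plaques_per_animal = 10), seed = 7)$truth)
  sp <- splitByAnimal(feat, seed = 2)
  m <- fitSVR(sp$train, cost_grid = 1, gamma_grid = 1, seed = 1)
  enc <- plaqueMorph:::.encodeDesign(sp$train, m@predictors)
  expect_equal(unname(m@center), unname(colMeans(enc$X)))
  sds <- apply(enc$X, 2, sd)
  sds[sds == 0] <- 1 # constant columns standardize with unit scale
  expect_equal(unname(m@scale), unname(sds))
  expect_equal(m@y_center, mean(sp$train$app_area_um2))
})

test_that("null predictors carry near-zero permutation importance over seeds", {
  imps <- t(sapply(1:10, function(s) {
    sim <- simulateCohort(cohortConfig(n_animals = 8, plaques_per_animal = 25),
                          seed = 100 + s)
    feat <- cohortFeatures(sim$truth)
    sp <- splitByAnimal(feat, seed = s)
    m <- fitSVR(sp$train, cost_grid = c(1, 10), gamma_grid = c(0.3, 1),
                seed = s)
    imp <- featureImportance(m, sp$test, n_permutations = 10, seed = s)
    # sex and age never enter the planted dystrophy model
    c(sex = imp$importance[imp$predictor == "sex"],
      age = imp$importance[imp$predictor == "age_months"])
  }))
  expect_lt(abs(mean(imps[, "sex"])), 0.02)
  expect_lt(abs(mean(imps[, "age"])), 0.02)
})

test_that("importance guards its permutation count and transfer guards leakage", {
  feat <- cohortFeatures(simulateCohort(
    cohortConfig(n_animals = 6, plaques_per_animal = 10), seed = 2)$truth)
  sp <- splitByAnimal(feat, seed = 3)
  m <- fitSVR(sp$train, cost_grid = 1, gamma_grid = 1, seed = 1)
  expect_error(featureImportance(m, sp$test, n_permutations = 0),
               "parameter error")
  expect_error(transferTest(m, sp$train), "leakage")
  expect_error(transferTest(m, sp$test[0, ]), "empty held-out")
  expect_silent(transferTest(m, sp$test))
})

test_that("exact linear data is fit exactly by the leverage regression", {
  d <- data.frame(x = seq(1, 10, by = 0.5))
  d$y <- 2 * d$x
  lf <- suppressWarnings(fitLinearLeverage(d, "y", "x"))
  est <- estimates(lf)
  expect_equal(est$estimate[est$term == "x"], 2, tolerance = 1e-12)
  expect_equal(unname(residuals(lf@fit)), rep(0, nrow(d)), tolerance = 1e-10)
})

test_that("planted coefficients are recovered within three standard errors", {
  set.seed(31)
  n <- 500
  d <- data.frame(hftaa = runif(n, 0, 10), qftaa = runif(n, 0, 10))
  d$y <- 1.5 * d$hftaa - 0.5 * d$qftaa + rnorm(n, 0, 0.1)
  lf <- fitLinearLeverage(d, "y", c("hftaa", "qftaa"))
  est <- estimates(lf)
  bh <- est[est$term == "hftaa", ]
  bq <- est[est$term == "qftaa", ]
  expect_lt(abs(bh$estimate - 1.5), 3 * bh$se)
  expect_lt(abs(bq$estimate + 0.5), 3 * bq$se)
})

test_that("leverage-residual pairs are centered at the data means", {
  set.seed(13)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  d$y <- 1 + d$a - 2 * d$b + rnorm(60, 0, 0.5)
  lf <- fitLinearLeverage(d, "y", c("a", "b", "c"))
  for (p in c("a", "b", "c")) {
    lev <- leverages(lf)[[p]]
    expect_equal(nrow(lev), 60)
    expect_equal(mean(lev$x_leverage), mean(d[[p]]))
    expect_equal(mean(lev$y_leverage), mean(d$y))
  }
})

test_that("OLS estimates match the closed-form normal-equation oracle", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30; p <- 3
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("u", "v", "w")))
    y <- rnorm(n)
    d <- data.frame(X, y = y)
    lf <- fitLinearLeverage(d, "y", c("u", "v", "w"))
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    expect_equal(estimates(lf)$estimate, as.vector(beta), tolerance = 1e-8)
  }
})

test_that("transforms and degenerate designs are rejected with clear errors", {
  d <- data.frame(x = 1:10, y = c(0, 2:10))
  expect_error(fitLinearLeverage(d, "y", "x", transform = "log10"),
               "positive response")
  expect_silent(fitLinearLeverage(d, "y", "x", transform = "log10p1"))
  d2 <- data.frame(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(fitLinearLeverage(d2, "y", c("x", "z")), "collinearity")
})
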