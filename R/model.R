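# Plaque-level predictive modeling: support vector regression of
# neuritic dystrophy with animal-grouped splits, cross-validated
# hyperparameters and permutation importance; plus effect-leverage
# ordinary least squares.

#' Default predictor set for the dystrophy model
#'
#' Sex, age, plaque-associated microglial (Iba1) area, qFTAA and hFTAA
#' areas, and the core qF/hF intensity ratio.
#' @export
dystrophyPredictors <- function() {
  c("sex", "age_months", "iba1_area_um2", "qftaa_area_um2",
    "hftaa_area_um2", "core_intensity_ratio_qf_hf")
}

# Encode predictors numerically; character/factor columns become 0/1
# indicator columns for all but the first (alphabetical) level. Level
# sets are taken from (or checked against) `levels_map` so train and
# test encodings agree.
.encodeDesign <- function(data, predictors, levels_map = NULL) {
  cols <- list()
  lm_out <- list()
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) .stopf("data error: predictor '%s' missing", p)
    if (is.numeric(v)) {
      cols[[p]] <- v
    } else {
      lv <- if (!is.null(levels_map[[p]])) levels_map[[p]]
            else sort(unique(as.character(v)))
      lm_out[[p]] <- lv
      for (l in lv[-1]) cols[[paste0(p, "_", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  if (any(!is.finite(X))) .stopf("data error: non-finite predictor values")
  list(X = X, levels = lm_out)
}

.r2 <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) .stopf("undefined-R^2 error: zero response variance")
  1 - sum((obs - pred)^2) / sst
}

#' Split a feature table at the animal level
#'
#' Randomly assigns whole groups (animals or patients), never individual
#' plaques, to training and testing partitions, so no animal contributes
#' to both.
#'
#' @param data feature data.frame.
#' @param group grouping column name.
#' @param train_fraction fraction of groups assigned to training.
#' @param seed integer seed; identical seeds give identical assignments.
#' @return List with \code{train}, \code{test} (data.frames) and
#'   \code{train_groups}, \code{test_groups}.
#' @export
splitByAnimal <- function(data, group = "animal_id", train_fraction = 0.8,
                          seed = 1L) {
  g <- unique(as.character(data[[group]]))
  if (length(g) < 2)
    .stopf("insufficient-groups error: need >= 2 groups, got %d", length(g))
  n_train <- round(train_fraction * length(g))
  n_train <- min(max(n_train, 1L), length(g) - 1L)
  tr_g <- .withSeed(seed, sample(g, n_train))
  te_g <- setdiff(g, tr_g)
  list(train = data[data[[group]] %in% tr_g, , drop = FALSE],
       test = data[data[[group]] %in% te_g, , drop = FALSE],
       train_groups = tr_g, test_groups = te_g)
}

#' Fit the dystrophy support vector regression
#'
#' Radial-kernel epsilon-SVR of the dystrophy response on the plaque
#' predictors. Predictors and response are standardized with statistics
#' computed from the training rows only; hyperparameters (cost and
#' kernel width) are selected over a small logarithmic grid by grouped
#' k-fold cross-validation, with folds cut at the animal level so no
#' animal straddles folds.
#'
#' @param train training data.frame.
#' @param response response column name (dystrophy area).
#' @param predictors predictor column names.
#' @param group grouping column name.
#' @param cv_folds number of grouped CV folds.
#' @param cost_grid,gamma_grid hyperparameter grids (gamma in units of
#'   1 / n_predictors).
#' @param epsilon SVR epsilon (on the standardized response).
#' @param seed integer seed for fold assignment.
#' @return A \linkS4class{ModelResult} with \code{r2_test} unset (NA).
#' @export
fitSVR <- function(train, response = "app_area_um2",
                   predictors = dystrophyPredictors(), group = "animal_id",
                   cv_folds = 5, cost_grid = c(1, 10, 100),
                   gamma_grid = c(0.3, 1, 3), epsilon = 0.1, seed = 1L) {
  enc <- .encodeDesign(train, predictors)
  X <- enc$X
  y <- train[[response]]
  if (any(!is.finite(y))) .stopf("data error: non-finite response values")
  g <- as.character(train[[group]])
  ug <- unique(g)
  if (length(ug) < cv_folds)
    .stopf("need >= %d groups in training for %d-fold grouped CV, got %d",
           cv_folds, cv_folds, length(ug))

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  y_ctr <- mean(y)
  y_scl <- stats::sd(y)
  constant_response <- !is.finite(y_scl) || y_scl == 0
  if (constant_response) y_scl <- 1
  ys <- (y - y_ctr) / y_scl

  if (constant_response) {
    # degenerate but legal: the model is the constant mean response
    return(new("ModelResult", model = NULL, predictors = predictors,
               response = response, group = group, center = ctr, scale = scl,
               y_center = y_ctr, y_scale = y_scl,
               folds = stats::setNames(integer(0), character(0)),
               best_params = list(cost = NA_real_, gamma = NA_real_,
                                  epsilon = epsilon, levels = enc$levels,
                                  constant = TRUE),
               cv_results = data.frame(), train_groups = ug,
               r2_test = NA_real_, importance = data.frame(),
               seed = as.integer(seed)))
  }

  # grouped folds: shuffled groups assigned round-robin
  folds <- .withSeed(seed, {
    perm <- sample(ug)
    stats::setNames(rep_len(seq_len(cv_folds), length(perm)), perm)
  })
  fold_of <- folds[g]

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid / ncol(X))
  grid$cv_r2 <- NA_real_
  for (i in seq_len(nrow(grid))) {
    r2s <- rep(NA_real_, cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold_of != f
      if (!any(tr) || !any(!tr)) next
      fit <- e1071::svm(Xs[tr, , drop = FALSE], ys[tr], type = "eps-regression",
                        kernel = "radial", cost = grid$cost[i],
                        gamma = grid$gamma[i], epsilon = epsilon,
                        scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
      obs <- ys[!tr]
      sst <- sum((obs - mean(obs))^2)
      if (sst > 0) r2s[f] <- 1 - sum((obs - pred)^2) / sst
    }
    grid$cv_r2[i] <- mean(r2s, na.rm = TRUE)
  }
  best <- which.max(grid$cv_r2)
  fit <- e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    epsilon = epsilon, scale = FALSE)
  new("ModelResult", model = fit, predictors = predictors,
      response = response, group = group, center = ctr, scale = scl,
      y_center = y_ctr, y_scale = y_scl, folds = as.integer(folds),
      best_params = list(cost = grid$cost[best], gamma = grid$gamma[best],
                         epsilon = epsilon, levels = enc$levels),
      cv_results = grid, train_groups = ug, r2_test = NA_real_,
      importance = data.frame(), seed = as.integer(seed))
}

#' Predict from a fitted dystrophy model
#'
#' @param object a \linkS4class{ModelResult}.
#' @param newdata data.frame with the predictor columns.
#' @return Numeric predictions on the response scale.
#' @export
predictModel <- function(object, newdata) {
  stopifnot(is(object, "ModelResult"))
  enc <- .encodeDesign(newdata, object@predictors,
                       levels_map = object@best_params$levels)
  if (isTRUE(object@best_params$constant))
    return(rep(object@y_center, nrow(enc$X)))
  Xs <- scale(enc$X, object@center, object@scale)
  as.numeric(stats::predict(object@model, Xs)) * object@y_scale +
    object@y_center
}

#' Held-out coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} between observed and predicted response on
#' a test partition.
#'
#' @param model a \linkS4class{ModelResult}.
#' @param test test data.frame (non-degenerate response variance).
#' @return R-squared (can be negative for models worse than the mean).
#' @export
evaluateR2 <- function(model, test) {
  .r2(test[[model@response]], predictModel(model, test))
}

#' Permutation feature importance with effect signs
#'
#' Importance of each predictor as the mean drop in test-set R-squared
#' when that predictor's column is permuted within animals (so group
#' structure is preserved), averaged over permutations. The sign of each
#' predictor's marginal effect comes from the slope of its
#' partial-dependence curve over the test data.
#'
#' @param model a \linkS4class{ModelResult}.
#' @param test test data.frame.
#' @param n_permutations permutations per predictor (>= 1).
#' @param seed integer seed.
#' @return data.frame with \code{predictor}, \code{importance},
#'   \code{pd_slope} and \code{sign}.
#' @export
featureImportance <- function(model, test, n_permutations = 100, seed = 1L) {
  if (n_permutations < 1)
    .stopf("parameter error: n_permutations must be >= 1")
  base_r2 <- evaluateR2(model, test)
  g <- as.character(test[[model@group]])
  out <- data.frame(predictor = model@predictors,
                    importance = NA_real_, pd_slope = NA_real_,
                    sign = NA_integer_, stringsAsFactors = FALSE)
  for (j in seq_along(model@predictors)) {
    p <- model@predictors[j]
    drops <- .withSeed(deriveSeed(seed, j), {
      vapply(seq_len(n_permutations), function(r) {
        perm <- test
        for (gg in unique(g)) {
          idx <- which(g == gg)
          perm[[p]][idx] <- perm[[p]][idx][sample(length(idx))]
        }
        base_r2 - .r2(perm[[model@response]], predictModel(model, perm))
      }, numeric(1))
    })
    out$importance[j] <- mean(drops)
    v <- test[[p]]
    if (is.numeric(v) && length(unique(v)) > 2) {
      qs <- unique(stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1)))
      pd <- vapply(qs, function(val) {
        d <- test; d[[p]] <- val
        mean(predictModel(model, d))
      }, numeric(1))
      out$pd_slope[j] <- unname(stats::coef(stats::lm(pd ~ qs))[2])
    } else {
      lv <- sort(unique(as.character(v)))
      if (length(lv) == 2) {
        pd <- vapply(lv, function(val) {
          d <- test; d[[p]] <- if (is.numeric(v)) as.numeric(val) else val
          mean(predictModel(model, d))
        }, numeric(1))
        out$pd_slope[j] <- pd[2] - pd[1]
      }
    }
    out$sign[j] <- sign(out$pd_slope[j])
  }
  out
}

#' Transfer test on a held-out group set
#'
#' Applies a trained model, without refitting, to plaques from groups
#' never seen in training (the cross-cohort generalizability protocol)
#' and reports the coefficient of determination.
#'
#' @param model a \linkS4class{ModelResult}.
#' @param heldout data.frame of held-out-group plaques.
#' @return R-squared on the held-out set.
#' @export
transferTest <- function(model, heldout) {
  if (nrow(heldout) == 0) .stopf("empty held-out set")
  hg <- unique(as.character(heldout[[model@group]]))
  overlap <- intersect(hg, model@train_groups)
  if (length(overlap))
    .stopf("leakage error: held-out groups overlap training groups (%s)",
           paste(overlap, collapse = ", "))
  evaluateR2(model, heldout)
}

#' Effect-leverage linear regression
#'
#' Ordinary least squares of an optionally log-transformed response on
#' one or more predictors, with per-predictor effect-leverage residual
#' pairs: for predictor X, the pair (residual of X on the remaining
#' predictors plus mean(X), residual of the transformed response on the
#' remaining predictors plus mean(Y)). The pair means therefore equal
#' (mean X, mean Y) exactly, and the least-squares line through the
#' pairs has the predictor's fitted coefficient as slope.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param predictors predictor column names (numeric).
#' @param transform response transform: \code{"identity"},
#'   \code{"log10"}, or \code{"log10p1"} (log10 of x + 1 for responses
#'   with zeros).
#' @return A \linkS4class{LeverageFit}.
#' @export
fitLinearLeverage <- function(data, response, predictors,
                              transform = c("identity", "log10", "log10p1")) {
  transform <- match.arg(transform)
  y <- data[[response]]
  y_t <- switch(transform,
                identity = y,
                log10 = {
                  if (any(y <= 0))
                    .stopf("log10 transform needs a positive response")
                  log10(y)
                },
                log10p1 = {
                  if (any(y < 0))
                    .stopf("log10[x+1] transform needs a non-negative response")
                  log10(y + 1)
                })
  X <- as.matrix(data[predictors])
  if (!is.numeric(X) || any(!is.finite(X)) || any(!is.finite(y_t)))
    .stopf("data error: predictors and transformed response must be finite")
  dd <- data.frame(.y = y_t, X)
  mm <- stats::model.matrix(~ ., data.frame(X))
  if (qr(mm)$rank < ncol(mm))
    .stopf("collinearity error: rank-deficient design")
  fit <- stats::lm(.y ~ ., data = dd)
  cf <- summary(fit)$coefficients
  est <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p = cf[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  lev <- list()
  for (p in predictors) {
    others <- setdiff(predictors, p)
    if (length(others)) {
      fx <- stats::lm(stats::reformulate(others, response = p),
                      data = data.frame(dd))
      fy <- stats::lm(stats::reformulate(others, response = ".y"),
                      data = dd)
      rx <- stats::residuals(fx); ry <- stats::residuals(fy)
    } else {
      rx <- dd[[p]] - mean(dd[[p]]); ry <- y_t - mean(y_t)
    }
    lev[[p]] <- data.frame(x_leverage = rx + mean(dd[[p]]),
                           y_leverage = ry + mean(y_t))
  }
  new("LeverageFit", fit = fit, transform = transform, estimates = est,
      leverages = lev)
}

# ---- accessors / show ------------------------------------------------------

#' @rdname r2Test
#' @export
setMethod("r2Test", "ModelResult", function(object) object@r2_test)

#' @rdname importances
#' @export
setMethod("importances", "ModelResult", function(object) object@importance)

#' @rdname leverages
#' @export
setMethod("leverages", "LeverageFit", function(object) object@leverages)

#' @rdname estimates
#' @export
setMethod("estimates", "LeverageFit", function(object) object@estimates)

setMethod("show", "ModelResult", function(object) {
  cat(sprintf(
    "ModelResult: SVR of %s on %d predictors, %d training groups\n",
    object@response, length(object@predictors),
    length(object@train_groups)))
  cat(sprintf("  cost %.3g, gamma %.4g; CV R^2 %.3f; test R^2 %s\n",
              object@best_params$cost, object@best_params$gamma,
              max(object@cv_results$cv_r2),
              if (is.na(object@r2_test)) "(not evaluated)"
              else sprintf("%.3f", object@r2_test)))
})

setMethod("show", "LeverageFit", function(object) {
  cat(sprintf("LeverageFit (%s response transform)\n", object@transform))
  print(object@estimates)
})
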