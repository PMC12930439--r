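# Standard-format I/O and end-to-end orchestration: TIFF scenes, CSV
# feature tables, YAML configuration, JSON model metadata.

.FEATURE_SCHEMA <- "plaqueMorph-feature-table v1"

#' Hash of a run configuration
#'
#' MD5 of the canonical deparse of the configuration list; stamped into
#' every output file so artifacts can be traced to the exact
#' configuration that produced them.
#'
#' @param config a configuration list.
#' @return Character MD5 hash.
#' @export
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config, control = c("all", "digits17")), f)
  unname(tools::md5sum(f))
}

#' Write a scene to disk as TIFF + JSON + CSV
#'
#' The hyperspectral stack goes to a multi-page TIFF (one 16-bit page per
#' band), each scalar channel to a single-page 16-bit TIFF (the RGB Congo
#' Red image keeps its three samples), the planted truth to CSV, and a
#' JSON manifest records the band grid, pixel size, channel inventory and
#' optional configuration hash. Intensities are snapped to the 16-bit
#' grid at generation time, so write/read round trips are bit-identical.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param dir output directory (created; one scene per directory).
#' @param config_hash optional hash stamped into the manifest.
#' @return Invisibly, the manifest path.
#' @export
writeScene <- function(scene, dir, config_hash = NULL) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scene_id = scene@scene_id,
                   pixel_size_um = scene@pixel_size_um,
                   channels = channelNames(scene),
                   config_hash = config_hash)
  for (nm in channelNames(scene)) {
    tiff::writeTIFF(scene@channels[[nm]], file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 16L, reduce = FALSE)
  }
  if (!is.null(scene@stack)) {
    g <- scene@stack@grid
    pages <- lapply(seq_len(nBands(g)), function(b) scene@stack@data[, , b])
    tiff::writeTIFF(pages, file.path(dir, "spectral_stack.tif"),
                    bits.per.sample = 16L, reduce = FALSE)
    manifest$band_grid <- list(start_nm = g@start_nm, step_nm = g@step_nm,
                               n_bands = g@n_bands)
  }
  utils::write.csv(scene@truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a scene written by \code{\link{writeScene}}
#'
#' Validates the manifest against expectations: the stack page count must
#' match the manifest's band grid (and \code{grid} if supplied), and
#' every manifest channel file must exist.
#'
#' @param dir scene directory.
#' @param grid optional expected \linkS4class{BandGrid}; a page-count
#'   mismatch is an error.
#' @return A \linkS4class{SyntheticScene}.
#' @export
readScene <- function(dir, grid = NULL) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) .stopf("format error: no manifest in '%s'", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  channels <- list()
  for (nm in manifest$channels) {
    f <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(f))
      .stopf("missing-channel error: manifest lists '%s' but %s is absent",
             nm, basename(f))
    img <- tiff::readTIFF(f)
    channels[[nm]] <- img
  }
  stack <- NULL
  spath <- file.path(dir, "spectral_stack.tif")
  if (file.exists(spath)) {
    pages <- tiff::readTIFF(spath, all = TRUE)
    bg <- manifest$band_grid
    g <- bandGrid(bg$start_nm, bg$step_nm, bg$n_bands)
    if (!is.null(grid)) {
      if (grid@n_bands != length(pages))
        .stopf("band-count error: stack has %d pages but grid expects %d",
               length(pages), grid@n_bands)
      g <- grid
    }
    if (length(pages) != g@n_bands)
      .stopf("band-count error: stack has %d pages but manifest grid has %d",
             length(pages), g@n_bands)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (b in seq_along(pages)) arr[, , b] <- pages[[b]]
    stack <- new("SpectralStack", data = arr, grid = g,
                 pixel_size_um = manifest$pixel_size_um)
  }
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  new("SyntheticScene", stack = stack, channels = channels,
      pixel_size_um = manifest$pixel_size_um, truth = truth,
      scene_id = manifest$scene_id)
}

#' Write / read the per-plaque feature table
#'
#' CSV with a schema-version header line (and the configuration hash when
#' given). Values round-trip to better than 1e-12 relative; the schema
#' version is checked on read.
#'
#' @param records feature data.frame.
#' @param path CSV path.
#' @param config_hash optional hash stamped into the header.
#' @return \code{writeFeatureTable}: invisibly, the path.
#'   \code{readFeatureTable}: the data.frame.
#' @export
writeFeatureTable <- function(records, path, config_hash = NULL) {
  hdr <- paste0("# ", .FEATURE_SCHEMA,
                if (!is.null(config_hash)) paste0(" hash=", config_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  is_num <- vapply(records, is.numeric, logical(1))
  fmt <- records
  fmt[is_num] <- lapply(records[is_num], function(x)
    sub("^\\s+", "", formatC(x, digits = 17, format = "g")))
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, paste0("# ", .FEATURE_SCHEMA)))
    .stopf("version error: unknown feature-table schema header '%s'", hdr)
  utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
}

#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: the cohort design, the
#' master seed, rendering mode, per-channel thresholds, the plaque-load
#' minimum size and per-plaque size gate, ROI dilation, and the model
#' settings.
#'
#' @param cohort a \code{\link{cohortConfig}} list.
#' @param seed master seed (required when simulation is enabled).
#' @param render \code{"channels"} or \code{"full"} (with spectral
#'   stacks; enables per-plaque spectral ratios).
#' @param thresholds named per-channel thresholds.
#' @param min_area_um2 plaque-load minimum component size.
#' @param gate_um2 closed per-plaque area gate \code{c(min, max)}.
#' @param dilate_um per-plaque ROI dilation radius.
#' @param model list of model settings (\code{train_fraction},
#'   \code{cv_folds}, \code{cost_grid}, \code{gamma_grid},
#'   \code{n_permutations}).
#' @return Configuration list.
#' @export
makeRunConfig <- function(cohort = cohortConfig(), seed = 1L,
                          render = c("channels", "full"),
                          thresholds = c(qftaa = 0.05, hftaa = 0.5,
                                         iba1 = 0.5, app = 0.5, ptau = 0.5,
                                         nfl = 0.5, cd68 = 0.5,
                                         trem2 = 0.02),
                          min_area_um2 = 30, gate_um2 = c(100, 2500),
                          dilate_um = 10,
                          model = list(train_fraction = 0.8, cv_folds = 5,
                                       cost_grid = c(1, 10, 100),
                                       gamma_grid = c(0.3, 1, 3),
                                       n_permutations = 20)) {
  render <- match.arg(render)
  cfg <- list(cohort = cohort, seed = seed, render = render,
              thresholds = as.list(thresholds), min_area_um2 = min_area_um2,
              gate_um2 = gate_um2, dilate_um = dilate_um, model = model)
  .validateRunConfig(cfg)
  cfg
}

.validateRunConfig <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    .stopf("config error: simulation requires a seed")
  thr <- unlist(cfg$thresholds)
  if (any(!is.finite(thr)))
    .stopf("config error: all thresholds must be finite")
  for (req in c("qftaa", "hftaa"))
    if (!req %in% names(cfg$thresholds))
      .stopf("config error: no threshold for channel '%s'", req)
  if (cfg$gate_um2[1] > cfg$gate_um2[2])
    .stopf("config error: gate minimum exceeds maximum")
  invisible(TRUE)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror \code{\link{makeRunConfig}}
#'   arguments (unknown keys are rejected), with \code{cohort} passed on
#'   to \code{\link{cohortConfig}}.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(makeRunConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    .stopf("config error: unknown keys: %s", paste(bad, collapse = ", "))
  if (!is.null(y$cohort)) y$cohort <- do.call(cohortConfig, y$cohort)
  if (!is.null(y$thresholds)) y$thresholds <- unlist(y$thresholds)
  do.call(makeRunConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulate (cohort with planted truth) -> render scenes -> segment the
#' hFTAA channel with the plaque-load filter -> apply the per-plaque size
#' gate -> extract features -> per-plaque spectral ratios (when spectral
#' stacks are rendered) -> animal-level split, SVR fit, held-out
#' R-squared and permutation importance. Outputs are reproducible under a
#' fixed configuration; when \code{out_dir} is given, the feature table
#' (CSV), model metadata (JSON) and configuration echo (YAML) are
#' written, each carrying the configuration hash.
#'
#' @param config list from \code{\link{makeRunConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param out_dir optional output directory.
#' @param quiet suppress per-stage messages.
#' @return List with \code{features}, \code{truth}, \code{model},
#'   \code{r2_test}, \code{importance}, \code{spectra} (or NULL) and
#'   \code{config_hash}.
#' @export
runPipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  .validateRunConfig(config)
  hash <- configHash(config)
  say <- function(fmt, ...) if (!quiet)
    message(sprintf(paste0("[plaqueMorph] ", fmt), ...))
  say("run %s (seed %d)", hash, config$seed)

  sim <- .stage("simulate", {
    simulateCohort(config$cohort, seed = config$seed,
                   render = if (config$render == "full") "full" else "channels")
  })
  say("simulate: %d animals, %d plaques", nrow(sim$truth@animals),
      nrow(sim$truth@plaques))

  feats <- list(); spectra <- list()
  for (aid in names(sim$scenes)) {
    sc <- sim$scenes[[aid]]
    labs <- .stage("segment", {
      segmentPlaques(getChannel(sc, "hftaa"), config$thresholds$hftaa,
                     min_area_um2 = config$min_area_um2,
                     pixel_size_um = pixelSize(sc))
    })
    gated <- .stage("gate",
                    gatePlaques(labs, config$gate_um2[1], config$gate_um2[2]))
    feats[[aid]] <- .stage("features", {
      extractFeatures(sc, gated, config$thresholds,
                      dilate_um = config$dilate_um, metadata = sim$metadata)
    })
    if (config$render == "full")
      spectra[[aid]] <- .stage("spectra", {
        sceneSpectralRatios(sc, qftaa_threshold = config$thresholds$qftaa)
      })
  }
  features <- do.call(rbind, c(feats, list(make.row.names = FALSE)))
  if (is.null(features)) features <- data.frame()
  spectra <- if (length(spectra))
    do.call(rbind, c(spectra, list(make.row.names = FALSE))) else NULL
  say("features: %d gated plaques", nrow(features))

  model <- NULL; r2 <- NA_real_; imp <- NULL
  n_groups <- length(unique(features$animal_id))
  if (n_groups >= max(2, config$model$cv_folds)) {
    sp <- .stage("model", {
      splitByAnimal(features, train_fraction = config$model$train_fraction,
                    seed = deriveSeed(config$seed, 101L))
    })
    model <- .stage("model", {
      fitSVR(sp$train, cv_folds = config$model$cv_folds,
             cost_grid = config$model$cost_grid,
             gamma_grid = config$model$gamma_grid,
             seed = deriveSeed(config$seed, 102L))
    })
    r2 <- .stage("model", evaluateR2(model, sp$test))
    imp <- .stage("model", {
      featureImportance(model, sp$test,
                        n_permutations = config$model$n_permutations,
                        seed = deriveSeed(config$seed, 103L))
    })
    model@r2_test <- r2
    model@importance <- imp
    say("model: test R^2 %.3f", r2)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeFeatureTable(features, file.path(out_dir, "features.csv"), hash)
    if (!is.null(spectra))
      writeFeatureTable(spectra, file.path(out_dir, "spectral_ratios.csv"),
                        hash)
    meta <- list(config_hash = hash, seed = config$seed,
                 n_plaques = nrow(features), r2_test = r2,
                 best_params = if (!is.null(model))
                   model@best_params[c("cost", "gamma", "epsilon")],
                 importance = imp)
    jsonlite::write_json(meta, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    yaml::write_yaml(c(list(config_hash = hash),
                       config[setdiff(names(config), "cohort")]),
                     file.path(out_dir, "config.yaml"))
  }
  list(features = features, truth = sim$truth, model = model, r2_test = r2,
       importance = imp, spectra = spectra, config_hash = hash)
}
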