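#' @import methods
NULL

#' Emission band grid
#'
#' Wavelength grid of a hyperspectral acquisition: evenly spaced emission
#' band centers starting at \code{start_nm} with spacing \code{step_nm}.
#' The default acquisition runs from 470 nm in 10.7 nm steps over 22 bands
#' (last band center 694.7 nm).
#'
#' @slot start_nm first band center in nanometres.
#' @slot step_nm band spacing in nanometres.
#' @slot n_bands number of bands.
#' @export
setClass("BandGrid", representation(
  start_nm = "numeric", step_nm = "numeric", n_bands = "integer"
))

setValidity("BandGrid", function(object) {
  if (length(object@start_nm) != 1 || length(object@step_nm) != 1 ||
      length(object@n_bands) != 1) return("slots must be scalars")
  if (object@n_bands < 2L) return("n_bands must be >= 2")
  if (object@step_nm <= 0) return("step_nm must be > 0 (strictly increasing grid)")
  TRUE
})

#' Dye basis spectra on a band grid
#'
#' Unit-maximum emission spectra of the two LCO binding states: the
#' compact-amyloid basis peaks at the band nearest \code{compact_peak_nm}
#' (qFTAA, 502 nm) and the filamentous basis carries two local maxima at
#' the bands nearest \code{filamentous_peaks_nm} (hFTAA, 545 and 588 nm),
#' the 588 nm one being global.
#'
#' @slot grid a \linkS4class{BandGrid}.
#' @slot compact per-band intensities of the compact basis.
#' @slot filamentous per-band intensities of the filamentous basis.
#' @slot compact_peak_nm nominal peak of the compact basis.
#' @slot filamentous_peaks_nm nominal local maxima of the filamentous basis.
#' @export
setClass("BasisSpectra", representation(
  grid = "BandGrid", compact = "numeric", filamentous = "numeric",
  compact_peak_nm = "numeric", filamentous_peaks_nm = "numeric"
))

setValidity("BasisSpectra", function(object) {
  nb <- object@grid@n_bands
  if (length(object@compact) != nb || length(object@filamentous) != nb)
    return("basis length must match grid")
  if (any(object@compact < 0) || any(object@filamentous < 0))
    return("bases must be non-negative")
  if (abs(max(object@compact) - 1) > 1e-12 ||
      abs(max(object@filamentous) - 1) > 1e-12)
    return("bases must be normalized to maximum 1")
  cen <- bandCenters(object@grid)
  if (which.max(object@compact) !=
      which.min(abs(cen - object@compact_peak_nm)))
    return("compact basis argmax not at band nearest its nominal peak")
  TRUE
})

#' Hyperspectral image stack
#'
#' A 3-D array (row, column, band) of emission intensities with a physical
#' pixel size and its band grid.
#'
#' @slot data numeric array \code{[rows, cols, bands]}.
#' @slot grid a \linkS4class{BandGrid}.
#' @slot pixel_size_um physical pixel edge length in micrometres.
#' @export
setClass("SpectralStack", representation(
  data = "array", grid = "BandGrid", pixel_size_um = "numeric"
))

setValidity("SpectralStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-D array (row, col, band)")
  if (d[3] != object@grid@n_bands) return("band dimension must match grid")
  if (object@pixel_size_um <= 0) return("pixel_size_um must be > 0")
  TRUE
})

#' Per-plaque emission spectrum
#'
#' Mean core emission spectrum of a single plaque on a fixed band grid,
#' optionally max-normalized (maximum exactly 1).
#'
#' @slot grid a \linkS4class{BandGrid}.
#' @slot intensities per-band non-negative intensities.
#' @slot normalized whether the spectrum is max-normalized.
#' @slot plaque_id identifier of the source plaque.
#' @export
setClass("EmissionSpectrum", representation(
  grid = "BandGrid", intensities = "numeric", normalized = "logical",
  plaque_id = "character"
))

setValidity("EmissionSpectrum", function(object) {
  if (length(object@intensities) != object@grid@n_bands)
    return("intensity length must match grid")
  if (any(object@intensities < 0)) return("intensities must be non-negative")
  if (isTRUE(object@normalized) &&
      abs(max(object@intensities) - 1) > 1e-12)
    return("normalized spectrum must have maximum exactly 1")
  TRUE
})

#' Synthetic microscopy scene
#'
#' One simulated field of view: an optional hyperspectral stack, a set of
#' co-registered scalar stain channels (plus an RGB Congo Red image), the
#' physical pixel size, and the slice of planted ground truth rendered
#' into this scene.
#'
#' @slot stack a \linkS4class{SpectralStack} or \code{NULL}.
#' @slot channels named list of 2-D matrices (\code{congo_rgb} is a
#'   3-D array with a trailing RGB dimension).
#' @slot pixel_size_um pixel edge length in micrometres.
#' @slot truth data.frame of planted per-plaque parameters for this scene.
#' @slot scene_id scene identifier.
#' @export
setClass("SyntheticScene", representation(
  stack = "ANY", channels = "list", pixel_size_um = "numeric",
  truth = "data.frame", scene_id = "character"
))

setValidity("SyntheticScene", function(object) {
  dims <- lapply(object@channels, function(ch) dim(ch)[1:2])
  if (length(dims) > 1 && !all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all channel images must share the same 2-D shape")
  if (!is.null(object@stack) &&
      !identical(dim(object@stack@data)[1:2], dims[[1]]))
    return("spectral stack shape must match channel shape")
  if (object@pixel_size_um <= 0) return("pixel_size_um must be > 0")
  TRUE
})

#' Planted cohort ground truth
#'
#' Everything the synthetic generator decided: the animal table (group,
#' age, sex), the per-plaque geometry and compaction, the planted linear
#' coefficients of the dystrophy channel on corona, microglia and core
#' areas, and the dystrophy noise scale. Parameter-recovery tests compare
#' measured quantities against this object.
#'
#' @slot seed master seed of the simulation.
#' @slot animals data.frame: \code{animal_id}, \code{group},
#'   \code{age_months}, \code{sex}.
#' @slot plaques data.frame of per-plaque truth (geometry, compaction,
#'   planted areas, linear predictor and realized dystrophy area).
#' @slot beta named numeric \code{c(h=, i=, q=)}: planted coefficients of
#'   dystrophy area on corona (filamentous-only), microglial and core area.
#' @slot noise_sigma dispersion of the dystrophy residual (um^2).
#' @slot group_compaction_shift named numeric per-group shift of mean
#'   compaction.
#' @slot pixel_size_um pixel edge length used for area quantization.
#' @slot config the generating configuration list.
#' @export
setClass("CohortTruth", representation(
  seed = "integer", animals = "data.frame", plaques = "data.frame",
  beta = "numeric", noise_sigma = "numeric",
  group_compaction_shift = "numeric", pixel_size_um = "numeric",
  config = "list"
))

setValidity("CohortTruth", function(object) {
  if (object@noise_sigma < 0) return("noise_sigma must be >= 0")
  if (!all(c("h", "i", "q") %in% names(object@beta)))
    return("beta must be named c(h=, i=, q=)")
  if (!all(object@plaques$animal_id %in% object@animals$animal_id))
    return("every plaque must map to exactly one listed animal")
  if (any(object@plaques$compaction_f < 0 | object@plaques$compaction_f > 1))
    return("compaction_f must lie in [0, 1]")
  if (any(object@plaques$corona_radius_um < object@plaques$core_radius_um))
    return("corona_radius must be >= core_radius")
  TRUE
})

#' Labeled plaque map
#'
#' 2-D label image from plaque segmentation: 0 is background and plaque k
#' carries label k. Labels are consecutive positive integers assigned in
#' raster-scan order of each component's first pixel.
#'
#' @slot labels integer matrix of labels.
#' @slot pixel_size_um pixel edge length in micrometres.
#' @slot provenance list recording channel, threshold, connectivity and
#'   active area gates.
#' @export
setClass("PlaqueLabelMap", representation(
  labels = "matrix", pixel_size_um = "numeric", provenance = "list"
))

setValidity("PlaqueLabelMap", function(object) {
  lv <- sort(unique(as.vector(object@labels)))
  lv <- lv[lv > 0]
  if (length(lv) && !identical(as.integer(lv), seq_along(lv)))
    return("labels must be consecutive positive integers")
  if (object@pixel_size_um <= 0) return("pixel_size_um must be > 0")
  TRUE
})

#' Fitted dystrophy regression model
#'
#' A support vector regression of plaque-level neuritic dystrophy with its
#' training-set standardization, grouped cross-validation folds, selected
#' hyperparameters, held-out performance and permutation importances.
#'
#' @slot model the fitted \code{e1071::svm} object.
#' @slot predictors predictor column names.
#' @slot response response column name.
#' @slot group grouping column name (animal or patient identifier).
#' @slot center,scale training-set standardization of the predictors.
#' @slot y_center,y_scale training-set standardization of the response.
#' @slot folds named integer vector mapping training group to CV fold.
#' @slot best_params selected hyperparameters.
#' @slot cv_results data.frame of the grid search (mean CV R-squared per
#'   hyperparameter combination).
#' @slot train_groups groups used in training.
#' @slot r2_test held-out R-squared (NA until evaluated).
#' @slot importance data.frame of permutation importances (may be empty).
#' @slot seed RNG seed used for folds and grid search.
#' @export
setClass("ModelResult", representation(
  model = "ANY", predictors = "character", response = "character",
  group = "character", center = "numeric", scale = "numeric",
  y_center = "numeric", y_scale = "numeric", folds = "integer",
  best_params = "list", cv_results = "data.frame",
  train_groups = "character", r2_test = "numeric", importance = "data.frame",
  seed = "integer"
))

setValidity("ModelResult", function(object) {
  if (length(object@r2_test) != 1) return("r2_test must be a scalar")
  if (!is.na(object@r2_test) && object@r2_test > 1)
    return("r2_test cannot exceed 1")
  TRUE
})

#' Effect-leverage linear regression fit
#'
#' Ordinary least squares on an optionally log-transformed response with
#' per-predictor effect-leverage residual pairs: the residuals of response
#' and predictor on the remaining predictors, with the response and
#' predictor means added back.
#'
#' @slot fit the underlying \code{lm} fit.
#' @slot transform response transform: \code{"identity"}, \code{"log10"}
#'   or \code{"log10p1"} (log10 of x + 1).
#' @slot estimates data.frame of coefficient estimates and standard errors.
#' @slot leverages named list of per-predictor data.frames with columns
#'   \code{x_leverage}, \code{y_leverage}.
#' @export
setClass("LeverageFit", representation(
  fit = "ANY", transform = "character", estimates = "data.frame",
  leverages = "list"
))

setValidity("LeverageFit", function(object) {
  n <- length(stats::residuals(object@fit))
  ok <- vapply(object@leverages, function(d) nrow(d) == n, logical(1))
  if (length(ok) && !all(ok))
    return("leverage residual count must equal row count")
  TRUE
})
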