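# Hyperspectral morphotype statistics: per-plaque core emission spectra
# and the 502/588 nm (dual stain) and 545/588 nm (single stain) ratios.

#' Automatic core ROI placement
#'
#' Places three circular regions of interest of fixed radius inside a
#' plaque core mask, emulating manual placement "within the middle core
#' region": candidate centers are the pixels that survive erosion of the
#' core mask by the ROI radius; the first center is the pixel deepest
#' inside the core (maximum distance transform) and the remaining two are
#' chosen by farthest-point sampling. Ties break in raster order, so
#' placement is deterministic. If the core is too small to erode, the ROI
#' radius collapses gracefully down to single-pixel ROIs.
#'
#' @param core_mask logical matrix marking core pixels.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param roi_radius_um ROI radius in micrometres.
#' @return List of three integer vectors of pixel indices (one per ROI),
#'   all inside the core mask.
#' @export
coreROIs <- function(core_mask, pixel_size_um = 0.5, roi_radius_um = 1.5) {
  if (!any(core_mask)) .stopf("empty-region error: core mask has no pixels")
  r_px <- max(round(roi_radius_um / pixel_size_um), 0L)
  # work inside the core's padded bounding box (results mapped back below)
  full_dim <- dim(core_mask)
  gi <- which(core_mask, arr.ind = TRUE)
  rw <- max(1L, min(gi[, 1]) - r_px - 1L):min(full_dim[1], max(gi[, 1]) + r_px + 1L)
  cw <- max(1L, min(gi[, 2]) - r_px - 1L):min(full_dim[2], max(gi[, 2]) + r_px + 1L)
  r_off <- rw[1] - 1L; c_off <- cw[1] - 1L
  core_mask <- core_mask[rw, cw, drop = FALSE]
  dmap <- EBImage::distmap(core_mask)
  centers_ok <- integer(0)
  while (r_px >= 0L && length(centers_ok) == 0L) {
    centers_ok <- which(dmap > r_px)
    if (length(centers_ok) == 0L) r_px <- r_px - 1L
  }
  d <- dim(core_mask)
  rc <- cbind((centers_ok - 1L) %% d[1] + 1L, (centers_ok - 1L) %/% d[1] + 1L)
  # first center: deepest pixel; then farthest-point sampling
  first <- centers_ok[order(-dmap[centers_ok], centers_ok)][1L]
  centers <- first
  while (length(centers) < 3L) {
    cr <- cbind((centers - 1L) %% d[1] + 1L, (centers - 1L) %/% d[1] + 1L)
    dist2 <- apply(rc, 1L, function(p)
      min((p[1] - cr[, 1])^2 + (p[2] - cr[, 2])^2))
    nxt <- centers_ok[order(-dist2, centers_ok)][1L]
    centers <- c(centers, nxt)
  }
  lapply(centers, function(ci) {
    cy <- (ci - 1L) %% d[1] + 1L
    cx <- (ci - 1L) %/% d[1] + 1L
    rr <- matrix(seq_len(d[1]), d[1], d[2])
    cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    px <- which((rr - cy)^2 + (cc - cx)^2 <= r_px^2 & core_mask)
    # map cropped indices back to the full image
    pr <- (px - 1L) %% d[1] + 1L + r_off
    pc <- (px - 1L) %/% d[1] + 1L + c_off
    (pc - 1L) * full_dim[1] + pr
  })
}

#' Mean core emission spectrum of a plaque
#'
#' Averages the stack spectrum over the pixels of each of the three core
#' ROIs, averages the three per-ROI mean spectra, and max-normalizes the
#' result (normalization is applied to the averaged spectrum, not per
#' ROI).
#'
#' @param stack a \linkS4class{SpectralStack}.
#' @param rois list of exactly three non-empty pixel-index vectors (as
#'   returned by \code{\link{coreROIs}}).
#' @param plaque_id identifier recorded on the spectrum.
#' @return A max-normalized \linkS4class{EmissionSpectrum}.
#' @export
plaqueCoreSpectrum <- function(stack, rois, plaque_id = "plaque") {
  stopifnot(is(stack, "SpectralStack"))
  if (length(rois) != 3L)
    .stopf("exactly 3 core ROIs are required, got %d", length(rois))
  if (any(lengths(rois) == 0L))
    .stopf("empty-region error: every ROI must contain >= 1 pixel")
  d <- dim(stack@data)
  plane_n <- d[1] * d[2]
  roi_means <- vapply(rois, function(px) {
    vapply(seq_len(d[3]), function(b)
      mean(stack@data[px + (b - 1L) * plane_n]), numeric(1))
  }, numeric(d[3]))
  spec <- rowMeans(roi_means)
  m <- max(spec)
  if (m <= 0) .stopf("degenerate-spectrum error: all-zero core spectrum")
  new("EmissionSpectrum", grid = stack@grid, intensities = spec / m,
      normalized = TRUE, plaque_id = as.character(plaque_id))
}

#' Emission spectrum constructor
#'
#' @param intensities per-band non-negative intensities.
#' @param grid a \linkS4class{BandGrid}.
#' @param normalize max-normalize the intensities.
#' @param plaque_id identifier.
#' @return An \linkS4class{EmissionSpectrum}.
#' @export
emissionSpectrum <- function(intensities, grid = bandGrid(),
                             normalize = TRUE, plaque_id = "plaque") {
  if (normalize) {
    m <- max(intensities)
    if (m <= 0) .stopf("degenerate-spectrum error: all-zero spectrum")
    intensities <- intensities / m
  }
  new("EmissionSpectrum", grid = grid, intensities = intensities,
      normalized = normalize, plaque_id = plaque_id)
}

#' Peak-ratio readout of an emission spectrum
#'
#' Intensity at the band nearest the numerator wavelength divided by the
#' intensity at the band nearest the denominator wavelength.
#' \code{ratio502to588} is the dual-stain readout (blue qFTAA peak over
#' red hFTAA peak: high for compacted, low for filamentous amyloid);
#' \code{ratio545to588} is the single-stain (hFTAA-only) readout using
#' its two local emission maxima.
#'
#' @param spectrum an \linkS4class{EmissionSpectrum} (max-normalized).
#' @param numerator_nm,denominator_nm readout wavelengths.
#' @return Dimensionless positive ratio.
#' @export
spectralRatio <- function(spectrum, numerator_nm, denominator_nm) {
  stopifnot(is(spectrum, "EmissionSpectrum"))
  num <- spectrum@intensities[bandIndex(spectrum@grid, numerator_nm)]
  den <- spectrum@intensities[bandIndex(spectrum@grid, denominator_nm)]
  if (den <= 0)
    .stopf("undefined-ratio error: zero intensity at the %g nm band",
           denominator_nm)
  num / den
}

#' @rdname spectralRatio
#' @export
ratio502to588 <- function(spectrum) spectralRatio(spectrum, 502, 588)

#' @rdname spectralRatio
#' @export
ratio545to588 <- function(spectrum) spectralRatio(spectrum, 545, 588)

#' Per-animal mean morphotype ratio
#'
#' Mean of the per-plaque spectral ratios of one animal, with a
#' below-minimum flag when fewer plaques than required contribute
#' (default 35 for the dual-stain readout; use 20 for the single-stain
#' mode).
#'
#' @param ratios numeric vector of per-plaque ratios from one animal.
#' @param min_plaques minimum plaque count for a reliable animal mean.
#' @return List with \code{mean}, \code{n} and \code{below_minimum}.
#' @export
animalMeanRatio <- function(ratios, min_plaques = 35) {
  if (length(ratios) == 0) .stopf("empty-input error: no ratios supplied")
  list(mean = mean(ratios), n = length(ratios),
       below_minimum = length(ratios) < min_plaques)
}

#' Spectral ratios of every plaque in a scene
#'
#' Full spectral readout of a rendered scene: thresholds the qFTAA
#' channel to find plaque cores, labels them, places three core ROIs per
#' plaque, computes each plaque's mean core emission spectrum and returns
#' the 502/588 (and 545/588) ratios. Cores are matched to planted truth
#' by position when truth is present.
#'
#' @param scene a \linkS4class{SyntheticScene} with a spectral stack.
#' @param qftaa_threshold threshold on the qFTAA channel defining cores
#'   (\code{core_source = "qftaa"}).
#' @param min_core_area_um2 minimum core area to attempt ROI placement.
#' @param roi_radius_um core ROI radius.
#' @param core_source where core regions come from: \code{"qftaa"}
#'   thresholds the qFTAA channel (only cores with compact signal are
#'   measurable, as on real images); \code{"truth"} uses the planted core
#'   geometry, which also covers fully filamentous cores that carry no
#'   qFTAA signal.
#' @return data.frame with one row per measured core: \code{plaque_id},
#'   \code{ratio_502_588}, \code{ratio_545_588}.
#' @export
sceneSpectralRatios <- function(scene, qftaa_threshold = 0.05,
                                min_core_area_um2 = 4,
                                roi_radius_um = 1.5,
                                core_source = c("qftaa", "truth")) {
  stopifnot(is(scene, "SyntheticScene"))
  core_source <- match.arg(core_source)
  if (is.null(scene@stack))
    .stopf("scene has no spectral stack; render with include_stack = TRUE")
  px <- scene@pixel_size_um
  d <- dim(scene@channels[[1]])[1:2]
  cores <- list(); pids <- character(0)
  if (core_source == "qftaa") {
    labs <- segmentPlaques(getChannel(scene, "qftaa"), qftaa_threshold,
                           min_area_um2 = min_core_area_um2,
                           pixel_size_um = px)
    lm <- labelMatrix(labs)
    for (k in seq_len(nPlaques(labs))) {
      core <- lm == k
      pid <- as.character(k)
      if (nrow(scene@truth)) {
        cen <- colMeans(which(core, arr.ind = TRUE))
        d2 <- (scene@truth$center_row - cen[1])^2 +
          (scene@truth$center_col - cen[2])^2
        pid <- scene@truth$plaque_id[which.min(d2)]
      }
      cores[[length(cores) + 1L]] <- core
      pids <- c(pids, pid)
    }
  } else {
    if (!nrow(scene@truth))
      .stopf("core_source = 'truth' needs planted truth in the scene")
    for (i in seq_len(nrow(scene@truth))) {
      tr <- scene@truth[i, ]
      n_core <- round(tr$core_area_um2 / px^2)
      if (n_core * px^2 < min_core_area_um2) next
      core <- matrix(FALSE, d[1], d[2])
      core[.discPixels(d, c(tr$center_row, tr$center_col), n_core)] <- TRUE
      cores[[length(cores) + 1L]] <- core
      pids <- c(pids, tr$plaque_id)
    }
  }
  if (!length(cores)) return(data.frame())
  out <- vector("list", length(cores))
  for (k in seq_along(cores)) {
    rois <- coreROIs(cores[[k]], px, roi_radius_um)
    spec <- plaqueCoreSpectrum(scene@stack, rois, plaque_id = pids[k])
    out[[k]] <- data.frame(plaque_id = pids[k],
                           ratio_502_588 = ratio502to588(spec),
                           ratio_545_588 = ratio545to588(spec),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

setMethod("show", "EmissionSpectrum", function(object) {
  cat(sprintf(
    "EmissionSpectrum '%s': %d bands%s, 502/588 = %.3f\n",
    object@plaque_id, nBands(object@grid),
    if (object@normalized) " (max-normalized)" else "",
    tryCatch(ratio502to588(object), error = function(e) NA_real_)))
})
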