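# Per-plaque morphometrics: LCO areas and ratios, core intensity ratio,
# normalized co-stain areas, colocalization, and overlap-vs-size curves.

# Dilate a logical mask by a disc of the given radius (in um).
.dilateMask <- function(mask, radius_um, pixel_size_um) {
  r_px <- round(radius_um / pixel_size_um)
  if (r_px < 1) return(mask)
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  EBImage::dilate(mask, brush) > 0
}

#' qFTAA / hFTAA area ratio
#'
#' Ratio of compact-amyloid (qFTAA) to filamentous-amyloid (hFTAA)
#' thresholded area per plaque; the area-based morphotype readout (high
#' for compacted plaques).
#'
#' @param record per-plaque record(s): a data.frame with columns
#'   \code{qftaa_area_um2} and \code{hftaa_area_um2}, or a numeric vector
#'   of qFTAA areas when \code{hftaa_area} is given.
#' @param hftaa_area hFTAA areas (when \code{record} is numeric).
#' @return Dimensionless ratio(s).
#' @export
lcoAreaRatio <- function(record, hftaa_area = NULL) {
  if (is.data.frame(record)) {
    q <- record$qftaa_area_um2; h <- record$hftaa_area_um2
  } else {
    q <- record; h <- hftaa_area
  }
  if (any(h <= 0))
    .stopf("undefined-ratio error: hFTAA area must be > 0")
  q / h
}

#' Core qFTAA / hFTAA intensity ratio
#'
#' Mean qFTAA intensity divided by mean hFTAA intensity over a plaque's
#' core region; the intensity-based morphotype readout.
#'
#' @param qftaa,hftaa channel image matrices.
#' @param core_mask logical matrix of core pixels (non-empty).
#' @return Dimensionless ratio.
#' @export
coreIntensityRatio <- function(qftaa, hftaa, core_mask) {
  if (!any(core_mask)) .stopf("empty-region error: core mask has no pixels")
  mh <- mean(hftaa[core_mask])
  if (mh <= 0) .stopf("undefined-ratio error: zero mean hFTAA intensity")
  mean(qftaa[core_mask]) / mh
}

#' Colocalization fraction
#'
#' Percentage of plaque material colocalized with a protein stain:
#' \code{100 * |protein & plaque| / |plaque|}. The plaque mask is by
#' convention the thresholded hFTAA channel united with the core, so the
#' whole plaque (including the qFTAA-positive core) is the denominator.
#'
#' @param protein_mask logical matrix of protein-positive pixels.
#' @param plaque_mask logical matrix of plaque pixels (non-empty).
#' @return Percent in \code{[0, 100]}.
#' @export
colocalizationFraction <- function(protein_mask, plaque_mask) {
  if (!identical(dim(protein_mask), dim(plaque_mask)))
    .stopf("shape error: mask shapes differ")
  n <- sum(plaque_mask)
  if (n == 0) .stopf("empty-region error: plaque mask has no pixels")
  100 * sum(protein_mask & plaque_mask) / n
}

#' Extract the per-plaque feature table from a scene
#'
#' For every gated plaque: plaque area (hFTAA-defined, core included),
#' qFTAA and hFTAA thresholded areas and their ratio, the core intensity
#' ratio (over the qFTAA-positive core), thresholded co-stain areas
#' measured inside the plaque mask dilated by \code{dilate_um}
#' (normalized by plaque area), Trem2 mean intensity, and the
#' colocalization fraction of \code{coloc_channel} with the plaque mask.
#' Animal metadata are joined from the scene truth.
#'
#' @param scene a \linkS4class{SyntheticScene} (or any object with the
#'   same channel layout).
#' @param labels a gated \linkS4class{PlaqueLabelMap} from the hFTAA
#'   channel.
#' @param thresholds named numeric vector/list of per-channel thresholds;
#'   must contain every requested channel and at least \code{qftaa} and
#'   \code{hftaa}.
#' @param dilate_um per-plaque ROI dilation radius in micrometres.
#' @param metadata optional animal table (\code{animal_id}, \code{group},
#'   \code{age_months}, \code{sex}) joined onto the records.
#' @param coloc_channel channel used for the colocalization fraction.
#' @return data.frame with one row per gated plaque.
#' @export
extractFeatures <- function(scene, labels, thresholds, dilate_um = 10,
                            metadata = NULL, coloc_channel = "app") {
  stopifnot(is(labels, "PlaqueLabelMap"))
  thresholds <- as.list(thresholds)
  for (req in c("qftaa", "hftaa"))
    if (is.null(thresholds[[req]]))
      .stopf("missing-channel error: no threshold for '%s'", req)
  px <- labels@pixel_size_um
  pa <- px^2
  lm <- labelMatrix(labels)
  n <- nPlaques(labels)
  ch_masks <- lapply(stats::setNames(nm = names(thresholds)), function(nm)
    getChannel(scene, nm) > thresholds[[nm]])
  costains <- setdiff(names(thresholds), c("qftaa", "hftaa"))
  truth <- scene@truth
  out <- vector("list", n)
  pad <- round(dilate_um / px) + 1L
  nr <- nrow(lm); nc <- ncol(lm)
  qimg <- getChannel(scene, "qftaa"); himg <- getChannel(scene, "hftaa")
  timg <- if ("trem2" %in% costains) getChannel(scene, "trem2") else NULL
  for (k in seq_len(n)) {
    # work inside the plaque's padded bounding box; everything measured is
    # within the dilated ROI, so cropping changes nothing but speed
    idx <- which(lm == k, arr.ind = TRUE)
    rw <- max(1L, min(idx[, 1]) - pad):min(nr, max(idx[, 1]) + pad)
    cw <- max(1L, min(idx[, 2]) - pad):min(nc, max(idx[, 2]) + pad)
    pm <- lm[rw, cw, drop = FALSE] == k
    roi <- .dilateMask(pm, dilate_um, px)
    qmask <- ch_masks$qftaa[rw, cw] & roi
    hmask <- ch_masks$hftaa[rw, cw] & roi
    plaque_mask <- hmask | qmask      # whole plaque incl. qFTAA core
    plaque_area <- sum(plaque_mask) * pa
    qarea <- sum(qmask) * pa
    harea <- sum(hmask) * pa
    cir <- if (any(qmask))
      coreIntensityRatio(qimg[rw, cw], himg[rw, cw], qmask)
    else NA_real_
    rec <- data.frame(
      plaque_id = as.character(k),
      plaque_area_um2 = plaque_area, qftaa_area_um2 = qarea,
      hftaa_area_um2 = harea,
      area_ratio_qf_hf = if (harea > 0) qarea / harea else NA_real_,
      core_intensity_ratio_qf_hf = cir,
      stringsAsFactors = FALSE)
    for (cs in costains) {
      a <- sum(ch_masks[[cs]][rw, cw] & roi) * pa
      rec[[paste0(cs, "_area_um2")]] <- a
      rec[[paste0(cs, "_area_norm")]] <- a / plaque_area
    }
    if ("trem2" %in% costains) {
      tm <- ch_masks$trem2[rw, cw] & roi
      rec$trem2_mean_intensity <- if (any(tm))
        mean(timg[rw, cw][tm]) else NA_real_
    }
    rec$coloc_fraction <- if (coloc_channel %in% names(ch_masks))
      colocalizationFraction(ch_masks[[coloc_channel]][rw, cw], plaque_mask)
    else NA_real_
    if (nrow(truth)) {
      cen <- colMeans(idx)
      d2 <- (truth$center_row - cen[1])^2 + (truth$center_col - cen[2])^2
      hit <- which.min(d2)
      rec$plaque_id <- truth$plaque_id[hit]
      rec$animal_id <- truth$animal_id[hit]
      rec$compaction_f_true <- truth$compaction_f[hit]
    }
    out[[k]] <- rec
  }
  if (n == 0L) return(data.frame())
  feat <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(metadata) && !is.null(feat$animal_id)) {
    m <- metadata[match(feat$animal_id, metadata$animal_id), ]
    feat$group <- m$group
    feat$age_months <- m$age_months
    feat$sex <- m$sex
  }
  feat
}

#' Signal overlap as a function of plaque size
#'
#' Bins plaques by area and reports the per-bin mean overlap percentage
#' of a first mask with a second (the colocalization fraction of mask 1
#' within mask 2), reproducing overlap-vs-size curves such as Congo Red
#' vs qFTAA or amyloid antibody vs hFTAA. Bin edges are a configuration
#' input; log-spaced edges over the plaque gate are a sensible default.
#'
#' @param mask_pairs list of per-plaque lists, each with elements
#'   \code{first} and \code{second} (logical matrices).
#' @param bin_edges increasing numeric vector of area bin edges (um^2).
#' @param pixel_size_um pixel edge length in micrometres.
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{mean_overlap}, \code{n} (empty bins carry \code{n = 0} and NA
#'   overlap).
#' @export
overlapBySize <- function(mask_pairs, bin_edges, pixel_size_um = 0.5) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    .stopf("parameter error: bin edges must be strictly increasing")
  pa <- pixel_size_um^2
  areas <- vapply(mask_pairs, function(p) sum(p$second) * pa, numeric(1))
  ovl <- vapply(mask_pairs, function(p)
    colocalizationFraction(p$first, p$second), numeric(1))
  bin <- cut(areas, bin_edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(bin_edges) - 1L
  data.frame(
    bin_lo = bin_edges[seq_len(nb)], bin_hi = bin_edges[-1L],
    mean_overlap = vapply(seq_len(nb), function(b)
      if (any(bin == b, na.rm = TRUE)) mean(ovl[which(bin == b)])
      else NA_real_, numeric(1)),
    n = vapply(seq_len(nb), function(b)
      sum(bin == b, na.rm = TRUE), numeric(1)))
}
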