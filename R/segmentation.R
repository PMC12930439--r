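# Plaque detection from scalar channels: fixed-threshold segmentation
# with a minimum-size load filter, closed-interval per-plaque size gating,
# CIELAB Congo Red detection and area fractions.

# Connected-component labeling. The 4-neighbourhood case is EBImage's
# labeller directly; the default 8-neighbourhood case merges 4-connected
# labels that touch diagonally with a union-find pass (EBImage labels
# 4-neighbourhoods only). Both paths are relabeled afterwards in
# raster-scan order of each component's first pixel, so labels are
# deterministic regardless of path.
.labelComponents <- function(mask, connectivity = 8L) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (!connectivity %in% c(4L, 8L))
    .stopf("connectivity must be 4 or 8, got %s", connectivity)
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    parent <- seq_len(max(lab))
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (d in list(c(-1L, -1L), c(-1L, 1L))) {
      # diagonal neighbour pairs: compare lab[r, c] with lab[r + dr, c + dc]
      r1 <- if (d[1] < 0) 2L:nr else seq_len(nr - 1L)
      c1 <- if (d[2] < 0) 2L:nc else seq_len(nc - 1L)
      x <- lab[r1, c1, drop = FALSE]
      y <- lab[r1 + d[1], c1 + d[2], drop = FALSE]
      sel <- x > 0L & y > 0L & x != y
      if (any(sel)) {
        pairs <- unique(cbind(x[sel], y[sel]))
        for (k in seq_len(nrow(pairs))) {
          ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    root <- vapply(seq_along(parent), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  .relabelRaster(lab)
}

# Relabel components consecutively in raster-scan (row-major) order of
# each component's first pixel.
.relabelRaster <- function(lab) {
  pos <- which(t(lab) > 0L)            # row-major scan positions
  if (!length(pos)) return(matrix(0L, nrow(lab), ncol(lab)))
  vals <- t(lab)[pos]
  first <- vals[!duplicated(vals)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0L] <- match(lab[lab > 0L], first)
  out
}

#' Segment plaques from a scalar channel
#'
#' Connected components of supra-threshold pixels (outside an optional
#' exclusion mask), with components below the minimum-size load filter
#' (default 30 um^2) removed. The exclusion mask replaces the manual
#' curation of misclassified objects and of vascular amyloid / high
#' background regions. Components are labeled consecutively in
#' raster-scan order of their first pixel.
#'
#' @param channel numeric image matrix.
#' @param threshold fixed intensity threshold; pixels strictly above it
#'   are foreground.
#' @param min_area_um2 minimum component area retained (closed bound:
#'   components of exactly this area are kept).
#' @param exclusion_mask optional logical matrix of pixels to ignore.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param connectivity neighbourhood for connectivity, 8 (default) or 4.
#' @return A \linkS4class{PlaqueLabelMap}.
#' @examples
#' img <- matrix(0, 40, 40); img[10:20, 10:20] <- 1
#' nPlaques(segmentPlaques(img, 0.5))
#' @export
segmentPlaques <- function(channel, threshold, min_area_um2 = 30,
                           exclusion_mask = NULL, pixel_size_um = 0.5,
                           connectivity = 8L) {
  stopifnot(is.matrix(channel))
  mask <- channel > threshold
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(channel)))
      .stopf("shape error: exclusion mask %s does not match channel %s",
             paste(dim(exclusion_mask), collapse = "x"),
             paste(dim(channel), collapse = "x"))
    mask <- mask & !exclusion_mask
  }
  lab <- .labelComponents(mask, connectivity)
  pa <- pixel_size_um^2
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L]) * pa
    keep <- which(sizes >= min_area_um2)
    lab[!(lab %in% keep)] <- 0L
    lab <- .relabelRaster(lab)
  }
  new("PlaqueLabelMap", labels = lab, pixel_size_um = pixel_size_um,
      provenance = list(threshold = threshold, min_area_um2 = min_area_um2,
                        connectivity = as.integer(connectivity)))
}

#' Congo Red mask via CIELAB thresholding
#'
#' Converts an RGB image to CIELAB (sRGB primaries, D65 white point) and
#' thresholds the a* (red-green) channel: pixels with a* strictly above
#' the threshold (default 0, i.e. any red purity) are Congo Red positive.
#' Saturated red is included; neutral grays (a* = 0) and greens (a* < 0)
#' are excluded.
#'
#' @param rgb numeric array \code{[rows, cols, 3]} with values in
#'   \code{[0, 1]}.
#' @param a_star_threshold threshold on the a* channel.
#' @return Logical matrix.
#' @export
congoRedMask <- function(rgb, a_star_threshold = 0) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    .stopf("format error: congoRedMask needs a 3-channel RGB image")
  d <- dim(rgb)
  flat <- cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                as.vector(rgb[, , 3]))
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  matrix(lab[, 2] > a_star_threshold, d[1], d[2])
}

#' Gate plaques by area
#'
#' Retains only components whose area lies in the closed interval
#' \code{[min_um2, max_um2]} (the per-plaque analysis gate, default
#' 100-2500 um^2; boundary plaques are retained) and relabels the
#' survivors consecutively.
#'
#' @param labels a \linkS4class{PlaqueLabelMap}.
#' @param min_um2,max_um2 closed area bounds in um^2.
#' @return A gated \linkS4class{PlaqueLabelMap}.
#' @export
gatePlaques <- function(labels, min_um2 = 100, max_um2 = 2500) {
  stopifnot(is(labels, "PlaqueLabelMap"))
  if (min_um2 > max_um2)
    .stopf("parameter error: min_um2 (%g) > max_um2 (%g)", min_um2, max_um2)
  lab <- labels@labels
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L]) * labels@pixel_size_um^2
    keep <- which(sizes >= min_um2 & sizes <= max_um2)
    lab[!(lab %in% keep)] <- 0L
    lab <- .relabelRaster(lab)
  }
  prov <- labels@provenance
  prov$gate_um2 <- c(min_um2, max_um2)
  new("PlaqueLabelMap", labels = lab, pixel_size_um = labels@pixel_size_um,
      provenance = prov)
}

#' Positive-area fraction of a region
#'
#' Percentage of a region covered by a positive mask:
#' \code{100 * |mask & region| / |region|} (areas in um^2 cancel).
#'
#' @param mask logical matrix of positive pixels.
#' @param region logical matrix defining the region (non-empty).
#' @param pixel_size_um pixel edge length in micrometres.
#' @return List with \code{positive_area_um2}, \code{region_area_um2} and
#'   \code{fraction} (percent).
#' @export
areaFraction <- function(mask, region, pixel_size_um = 0.5) {
  if (!identical(dim(mask), dim(region)))
    .stopf("shape error: mask and region shapes differ")
  n_reg <- sum(region)
  if (n_reg == 0) .stopf("empty-region error: region has no pixels")
  pa <- pixel_size_um^2
  n_pos <- sum(mask & region)
  list(positive_area_um2 = n_pos * pa, region_area_um2 = n_reg * pa,
       fraction = 100 * n_pos / n_reg)
}

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "PlaqueLabelMap", function(object) object@labels)

#' @rdname nPlaques
#' @export
setMethod("nPlaques", "PlaqueLabelMap",
          function(object) max(object@labels))

#' @rdname plaqueAreas
#' @export
setMethod("plaqueAreas", "PlaqueLabelMap", function(object) {
  lab <- object@labels
  if (max(lab) == 0L) return(stats::setNames(numeric(0), character(0)))
  a <- tabulate(lab[lab > 0L]) * object@pixel_size_um^2
  stats::setNames(a, seq_along(a))
})

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "PlaqueLabelMap", function(object) object@pixel_size_um)

setMethod("show", "PlaqueLabelMap", function(object) {
  cat(sprintf("PlaqueLabelMap: %d plaques, %dx%d px (%.2f um/px)\n",
              nPlaques(object), nrow(object@labels), ncol(object@labels),
              object@pixel_size_um))
})
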