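# Autoradiography quantification: background-subtracted cortex to
# white-matter (reference) intensity ratios, and a simulator whose tracer
# binding is proportional to planted compact (core) amyloid area only.

#' Cortex-to-reference ROI ratio
#'
#' Background-subtracted intensity ratio of a cortical ROI to a
#' white-matter reference ROI:
#' \code{(mean(cortex) - background) / (mean(reference) - background)}.
#'
#' @param image intensity matrix.
#' @param cortex_roi,reference_roi non-empty, disjoint logical masks.
#' @param background scalar background intensity.
#' @param section_id identifier recorded in the result.
#' @return List with \code{section_id}, \code{cortex_mean},
#'   \code{reference_mean}, \code{background} and \code{ratio}.
#' @export
roiRatio <- function(image, cortex_roi, reference_roi, background = 0,
                     section_id = "section") {
  if (!any(cortex_roi) || !any(reference_roi))
    .stopf("empty-region error: both ROIs must be non-empty")
  if (any(cortex_roi & reference_roi))
    .stopf("roi-overlap error: cortex and reference ROIs overlap")
  cm <- mean(image[cortex_roi])
  rm_ <- mean(image[reference_roi])
  if (rm_ - background <= 0)
    .stopf("undefined-ratio error: reference at or below background")
  list(section_id = section_id, cortex_mean = cm, reference_mean = rm_,
       background = background, ratio = (cm - background) / (rm_ - background))
}

#' Simulate autoradiography sections for a cohort
#'
#' Generates one tracer-binding image per animal in which cortical
#' intensity is proportional to the animal's summed planted compact
#' (core) amyloid area — the tracer binds compacted fibrils only, so
#' filamentous-only (corona) amyloid contributes nothing — while the
#' white-matter reference region sits at baseline:
#' \code{cortex = baseline * (1 + gain * total_core_area) + noise}. At
#' zero noise and zero compact area the cortex/reference ratio is exactly
#' 1, and (ratio - 1) is linear in total compact area.
#'
#' @param truth a \linkS4class{CohortTruth}, or a data.frame with columns
#'   \code{animal_id}, \code{core_area_um2} and (optionally)
#'   \code{corona_area_um2} giving per-animal totals.
#' @param gain tracer-binding gain per um^2 of compact amyloid.
#' @param baseline tissue baseline intensity.
#' @param background additive plate background (applied to the whole
#'   image; removed again by \code{\link{roiRatio}}).
#' @param noise_sd additive image noise SD.
#' @param seed integer seed.
#' @param img_dim image dimensions (rows, cols); the left half is
#'   cortex, the right half white matter.
#' @return List with \code{sections} (per-animal list of \code{image},
#'   \code{cortex_roi}, \code{reference_roi}), \code{truth} (per-animal
#'   planted totals) and \code{measured} (data.frame of ratios from
#'   \code{\link{roiRatio}}).
#' @export
simulateAutorad <- function(truth, gain = 5e-5, baseline = 0.2,
                            background = 0.05, noise_sd = 0, seed = 1L,
                            img_dim = c(48, 64)) {
  per_animal <- if (is(truth, "CohortTruth")) {
    plq <- truth@plaques
    agg <- stats::aggregate(
      cbind(core_area_um2, corona_area_um2) ~ animal_id, data = plq, FUN = sum)
    agg
  } else {
    stopifnot(is.data.frame(truth), all(c("animal_id", "core_area_um2") %in%
                                          names(truth)))
    truth
  }
  half <- img_dim[2] %/% 2
  cortex_roi <- matrix(FALSE, img_dim[1], img_dim[2])
  cortex_roi[, seq_len(half)] <- TRUE
  reference_roi <- !cortex_roi
  sections <- vector("list", nrow(per_animal))
  measured <- vector("list", nrow(per_animal))
  for (a in seq_len(nrow(per_animal))) {
    img <- .withSeed(deriveSeed(seed, a), {
      m <- matrix(baseline, img_dim[1], img_dim[2])
      m[cortex_roi] <- baseline * (1 + gain * per_animal$core_area_um2[a])
      m <- m + background
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      m
    })
    sections[[a]] <- list(image = img, cortex_roi = cortex_roi,
                          reference_roi = reference_roi)
    r <- roiRatio(img, cortex_roi, reference_roi, background,
                  section_id = per_animal$animal_id[a])
    measured[[a]] <- data.frame(animal_id = per_animal$animal_id[a],
                                ratio = r$ratio,
                                cortex_mean = r$cortex_mean,
                                reference_mean = r$reference_mean)
  }
  names(sections) <- per_animal$animal_id
  list(sections = sections, truth = per_animal,
       measured = do.call(rbind, c(measured, list(make.row.names = FALSE))))
}
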