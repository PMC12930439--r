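#' Construct an emission band grid
#'
#' Defaults reproduce a spectral-detector acquisition from 470 nm in
#' 10.7 nm steps over 22 bands (band centers 470.0, 480.7, ..., 694.7 nm),
#' which places band centers within 0.3 nm of the 502, 545 and 588 nm
#' readout wavelengths.
#'
#' @param start_nm first band center in nanometres.
#' @param step_nm band spacing in nanometres.
#' @param n_bands number of bands.
#' @return A \linkS4class{BandGrid}.
#' @examples
#' g <- bandGrid()
#' bandCenters(g)[c(4, 8, 12)] # 502.1, 544.9, 587.7
#' @export
bandGrid <- function(start_nm = 470, step_nm = 10.7, n_bands = 22L) {
  new("BandGrid", start_nm = start_nm, step_nm = step_nm,
      n_bands = as.integer(n_bands))
}

#' @rdname bandCenters
#' @export
setMethod("bandCenters", "BandGrid", function(object) {
  object@start_nm + (seq_len(object@n_bands) - 1L) * object@step_nm
})

#' @rdname nBands
#' @export
setMethod("nBands", "BandGrid", function(object) object@n_bands)

setMethod("show", "BandGrid", function(object) {
  cen <- bandCenters(object)
  cat(sprintf("BandGrid: %d bands, %.1f-%.1f nm, step %.2f nm\n",
              object@n_bands, cen[1], cen[length(cen)], object@step_nm))
})

#' Index of the band nearest a target wavelength
#'
#' Nearest-band lookup on the grid (no spectral interpolation); ties are
#' broken toward the lower wavelength. On the default grid, 502 nm maps to
#' band 4 (center 502.1 nm), 545 nm to band 8 (544.9 nm) and 588 nm to
#' band 12 (587.7 nm).
#'
#' @param grid a \linkS4class{BandGrid}.
#' @param target_nm target wavelength in nanometres; must fall within the
#'   grid span extended by half a step on each side.
#' @return 1-based band index.
#' @export
bandIndex <- function(grid, target_nm) {
  stopifnot(is(grid, "BandGrid"), length(target_nm) == 1)
  cen <- bandCenters(grid)
  half <- grid@step_nm / 2
  if (target_nm < cen[1] - half || target_nm > cen[length(cen)] + half)
    .stopf("target wavelength %.1f nm outside grid span [%.1f, %.1f] nm",
           target_nm, cen[1] - half, cen[length(cen)] + half)
  which.min(abs(cen - target_nm)) # which.min takes the first (lower) tie
}

#' Generate the dye basis spectra on a band grid
#'
#' Builds the two unit-maximum emission bases used by the scene simulator:
#' a compact-amyloid basis (single Gaussian bump peaking at the band
#' nearest 502 nm, the qFTAA readout peak) and a filamentous basis (sum of
#' two Gaussian bumps with local maxima at the bands nearest 545 and
#' 588 nm, the hFTAA readout maxima, the 588 nm one being global). Peak
#' positions are pinned to the nearest band centers; bump widths and the
#' relative height of the 545 nm shoulder are free simulation parameters.
#'
#' @param grid a \linkS4class{BandGrid} with at least 4 bands.
#' @param compact_sd_nm Gaussian width of the compact basis (nm).
#' @param filamentous_sd_nm widths of the 545 and 588 nm bumps (nm).
#' @param shoulder relative height of the 545 nm bump.
#' @return A \linkS4class{BasisSpectra}.
#' @examples
#' b <- makeBasisSpectra(bandGrid())
#' which.max(b@compact)      # band nearest 502 nm
#' which.max(b@filamentous)  # band nearest 588 nm
#' @export
makeBasisSpectra <- function(grid = bandGrid(), compact_sd_nm = 30,
                             filamentous_sd_nm = c(12, 16),
                             shoulder = 0.9) {
  stopifnot(is(grid, "BandGrid"))
  if (grid@n_bands < 4L)
    .stopf("invalid grid: basis generation needs at least 4 bands, got %d",
           grid@n_bands)
  cen <- bandCenters(grid)
  peak_c <- cen[bandIndex(grid, 502)]
  peak_f1 <- cen[bandIndex(grid, 545)]
  peak_f2 <- cen[bandIndex(grid, 588)]
  gauss <- function(mu, sd) exp(-((cen - mu)^2) / (2 * sd^2))
  compact <- gauss(peak_c, compact_sd_nm)
  compact <- compact / max(compact)
  fil <- shoulder * gauss(peak_f1, filamentous_sd_nm[1]) +
    gauss(peak_f2, filamentous_sd_nm[2])
  fil <- fil / max(fil)
  new("BasisSpectra", grid = grid, compact = compact, filamentous = fil,
      compact_peak_nm = 502, filamentous_peaks_nm = c(545, 588))
}

setMethod("show", "BasisSpectra", function(object) {
  cen <- bandCenters(object@grid)
  cat(sprintf(
    "BasisSpectra on %d bands: compact peak %.1f nm, filamentous max %.1f nm\n",
    object@grid@n_bands, cen[which.max(object@compact)],
    cen[which.max(object@filamentous)]))
})
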