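# Synthetic hyperspectral plaque scenes with planted ground truth.
#
# Plaques are rendered as a compact disc core inside an annular
# filamentous corona. Discs are area-exact: a disc of planted area A at
# pixel size p covers exactly round(A / p^2) pixels (the pixels nearest
# the center, ties broken in raster order), so planted areas, size gates
# and downstream area oracles are exact rather than approximate.

# Exactly n_px pixels nearest `center`, ties broken by raster order.
.discPixels <- function(dim, center, n_px) {
  if (n_px <= 0) return(integer(0))
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  order(as.vector(d2))[seq_len(min(n_px, length(d2)))]
}

# n_px pixels whose distance from `center` is nearest `r0_px`: an annular
# band straddling the radius r0_px (used for dystrophic boutons around the
# plaque border).
.straddlePixels <- function(dim, center, n_px, r0_px) {
  if (n_px <= 0) return(integer(0))
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  order(as.vector(abs(d - r0_px)))[seq_len(min(n_px, length(d)))]
}

# n_px pixels nearest `center` among those strictly outside radius r0_px
# (microglial annulus hugging the corona).
.ringPixels <- function(dim, center, n_px, r0_px) {
  if (n_px <= 0) return(integer(0))
  rr <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cc <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  d2 <- as.vector((rr - center[1])^2 + (cc - center[2])^2)
  out <- which(d2 > r0_px^2)
  out[order(d2[out])][seq_len(min(n_px, length(out)))]
}

.noisy <- function(img, noise_sd) {
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  .q16(.clamp01(img))
}

#' Construct a single-plaque truth row
#'
#' Convenience constructor for one planted plaque, specified by total
#' (corona-bounded) area and the fraction of that area occupied by the
#' compact core. Areas are quantized to whole pixels so that rendering is
#' area-exact.
#'
#' @param plaque_id identifier.
#' @param area_um2 total plaque area (core + corona) in um^2.
#' @param core_fraction fraction of the plaque area occupied by the core.
#' @param compaction_f weight of the compact basis in the core spectrum,
#'   in \code{[0, 1]}.
#' @param iba1_area_um2 planted plaque-associated microglial area (um^2).
#' @param app_area_um2 planted dystrophy (APP) area (um^2); set NA when
#'   \code{\link{renderCostains}} is asked to compute it from coefficients.
#' @param pixel_size_um pixel edge length (um) used for quantization.
#' @return A one-row data.frame of planted plaque parameters.
#' @export
makePlaqueTruth <- function(plaque_id = "p1", area_um2 = 400,
                            core_fraction = 0.25, compaction_f = 0.6,
                            iba1_area_um2 = 0.4 * area_um2,
                            app_area_um2 = 0,
                            pixel_size_um = 0.5) {
  if (compaction_f < 0 || compaction_f > 1)
    .stopf("compaction_f must lie in [0, 1], got %g", compaction_f)
  area <- .pxArea(area_um2, pixel_size_um)
  core <- .pxArea(core_fraction * area_um2, pixel_size_um)
  data.frame(
    plaque_id = plaque_id, animal_id = NA_character_,
    core_radius_um = sqrt(core / pi), corona_radius_um = sqrt(area / pi),
    compaction_f = compaction_f, area_um2 = area,
    core_area_um2 = core, corona_area_um2 = area - core,
    iba1_area_um2 = .pxArea(iba1_area_um2, pixel_size_um),
    app_area_um2 = if (is.na(app_area_um2)) NA_real_
                   else .pxArea(app_area_um2, pixel_size_um),
    stringsAsFactors = FALSE)
}

# Tile edge (pixels, odd) large enough to hold the plaque, its microglial
# annulus, the dystrophy band and the downstream ROI dilation.
.tileEdge <- function(truth, pixel_size_um, dilate_um = 10, margin_um = 3) {
  r_p <- sqrt(truth$area_um2 / pi)
  r_iba <- sqrt((truth$area_um2 + truth$iba1_area_um2) / pi)
  app <- ifelse(is.na(truth$app_area_um2), 0, truth$app_area_um2)
  r_app <- sqrt((truth$area_um2 + app) / pi)
  r_need <- max(r_p + dilate_um, r_iba, r_app) + margin_um
  2L * as.integer(ceiling(r_need / pixel_size_um)) + 1L
}

#' Render the co-stain channels of one plaque
#'
#' Renders the scalar stain channels around a planted plaque: qFTAA
#' (compact core, intensity equal to the compaction fraction), hFTAA and
#' amyloid antibody (whole plaque), an RGB Congo Red image (red over the
#' core only, neutral gray elsewhere), a microglial Iba1 annulus hugging
#' the corona with the planted area, a dystrophy (APP) bouton band
#' straddling the plaque border whose thresholded area equals
#' \code{beta["h"] * corona + beta["i"] * iba1 + beta["q"] * core + eps}
#' clipped at zero (or the pre-planted \code{app_area_um2} when
#' \code{beta} is NULL), plus pTau/NfL subsets of the dystrophy band,
#' a CD68 subset of the microglial annulus, and a Trem2 intensity field
#' on the annulus.
#'
#' @param truth one-row truth data.frame (see \code{\link{makePlaqueTruth}}).
#' @param pixel_size_um pixel edge length in micrometres.
#' @param dim image dimensions (rows, cols); defaults to a tile sized to
#'   contain all rendered structures.
#' @param center plaque center (row, col); defaults to the tile center.
#' @param beta named coefficients \code{c(h=, i=, q=)} of the dystrophy
#'   area on corona, microglial and core area, or NULL to use the planted
#'   \code{app_area_um2}.
#' @param noise_sigma dystrophy residual SD in um^2 (used with
#'   \code{beta}).
#' @param noise_sd additive image noise SD (intensity units, truncated so
#'   intensities stay in \code{[0, 1]}).
#' @param rng_seed integer seed for this tile's RNG stream.
#' @param trem2_intensity Trem2 staining intensity on the annulus.
#' @return Named list of channel images (matrices; \code{congo_rgb} is a
#'   3-D array).
#' @export
renderCostains <- function(truth, pixel_size_um = 0.5, dim = NULL,
                           center = NULL, beta = NULL, noise_sigma = 0,
                           noise_sd = 0, rng_seed = 1L,
                           trem2_intensity = 0.5) {
  stopifnot(nrow(truth) == 1)
  if (!is.null(beta)) {
    if (!all(is.finite(beta)) || !all(c("h", "i", "q") %in% names(beta)))
      .stopf("beta must be finite and named c(h=, i=, q=)")
    if (noise_sigma < 0) .stopf("noise_sigma must be >= 0")
  }
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  pa <- pixel_size_um^2
  if (is.null(dim)) {
    e <- .tileEdge(truth, pixel_size_um)
    dim <- c(e, e)
  }
  if (is.null(center)) center <- (dim + 1) / 2
  .withSeed(rng_seed, {
    n_core <- round(truth$core_area_um2 / pa)
    n_plq <- round(truth$area_um2 / pa)
    n_iba <- round(truth$iba1_area_um2 / pa)
    app_um2 <- if (is.null(beta)) {
      if (is.na(truth$app_area_um2))
        .stopf("truth$app_area_um2 is NA and no beta given")
      truth$app_area_um2
    } else {
      eta <- beta[["h"]] * truth$corona_area_um2 +
        beta[["i"]] * truth$iba1_area_um2 +
        beta[["q"]] * truth$core_area_um2
      max(eta + if (noise_sigma > 0) stats::rnorm(1, 0, noise_sigma) else 0, 0)
    }
    n_app <- round(app_um2 / pa)

    core_px <- .discPixels(dim, center, n_core)
    plq_px <- .discPixels(dim, center, n_plq)
    r_plq_px <- sqrt(n_plq * pa / pi) / pixel_size_um
    iba_px <- .ringPixels(dim, center, n_iba, r_plq_px)
    app_px <- .straddlePixels(dim, center, n_app, r_plq_px)

    blank <- matrix(0, dim[1], dim[2])
    ch <- list()
    q <- blank; q[core_px] <- truth$compaction_f
    h <- blank; h[plq_px] <- 1
    ab <- blank; ab[plq_px] <- 1
    iba <- blank; iba[iba_px] <- 1
    app <- blank; app[app_px] <- 1
    ptau <- blank; ptau[app_px[seq_len(round(0.6 * n_app))]] <- 1
    nfl <- blank; nfl[app_px[seq_len(round(0.4 * n_app))]] <- 1
    cd68 <- blank; cd68[iba_px[seq_len(round(0.5 * n_iba))]] <- 1
    trem2 <- blank; trem2[iba_px] <- trem2_intensity

    rgb <- array(0.5, c(dim[1], dim[2], 3))
    r_ch <- rgb[, , 1]; g_ch <- rgb[, , 2]; b_ch <- rgb[, , 3]
    r_ch[core_px] <- 0.75; g_ch[core_px] <- 0.15; b_ch[core_px] <- 0.15
    rgb[, , 1] <- .noisy(r_ch, noise_sd)
    rgb[, , 2] <- .noisy(g_ch, noise_sd)
    rgb[, , 3] <- .noisy(b_ch, noise_sd)

    list(qftaa = .noisy(q, noise_sd), hftaa = .noisy(h, noise_sd),
         abeta = .noisy(ab, noise_sd), congo_rgb = rgb,
         iba1 = .noisy(iba, noise_sd), app = .noisy(app, noise_sd),
         ptau = .noisy(ptau, noise_sd), nfl = .noisy(nfl, noise_sd),
         cd68 = .noisy(cd68, noise_sd), trem2 = .noisy(trem2, noise_sd))
  })
}

#' Render one plaque as a synthetic scene tile
#'
#' Renders the hyperspectral stack of a planted plaque — core pixels carry
#' the spectrum \code{f * compact + (1 - f) * filamentous}, corona pixels
#' the filamentous basis only, scaled to a peak intensity
#' \code{signal_level} — together with all co-stain channels. Additive
#' Gaussian noise (SD \code{noise_sd}) is applied and intensities are
#' clamped to \code{[0, 1]} and snapped to the 16-bit storage grid, so
#' identical seeds yield bit-identical tiles and TIFF round trips are
#' exact.
#'
#' @inheritParams renderCostains
#' @param bases a \linkS4class{BasisSpectra}.
#' @param include_stack render the hyperspectral stack (set FALSE for
#'   large cohorts where only scalar channels are needed).
#' @param signal_level peak spectral intensity of plaque material.
#' @return A \linkS4class{SyntheticScene} tile.
#' @examples
#' tr <- makePlaqueTruth(area_um2 = 400, compaction_f = 1)
#' tile <- renderPlaque(tr, makeBasisSpectra())
#' @export
renderPlaque <- function(truth, bases, pixel_size_um = 0.5, noise_sd = 0,
                         rng_seed = 1L, dim = NULL, center = NULL,
                         include_stack = TRUE, signal_level = 0.8,
                         beta = NULL, noise_sigma = 0,
                         trem2_intensity = 0.5) {
  stopifnot(is(bases, "BasisSpectra"), nrow(truth) == 1)
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  f <- truth$compaction_f
  if (f < 0 || f > 1) .stopf("compaction_f must lie in [0, 1]")
  pa <- pixel_size_um^2
  if (round(truth$area_um2 / pa) < 1)
    .stopf("plaque area %g um^2 not expressible in >= 1 pixel", truth$area_um2)
  if (is.null(dim)) {
    e <- .tileEdge(truth, pixel_size_um)
    dim <- c(e, e)
  }
  if (is.null(center)) center <- (dim + 1) / 2

  channels <- renderCostains(truth, pixel_size_um, dim, center, beta,
                             noise_sigma, noise_sd,
                             rng_seed = deriveSeed(rng_seed, 2L),
                             trem2_intensity = trem2_intensity)
  stack <- NULL
  if (include_stack) {
    nb <- nBands(bases@grid)
    core_px <- .discPixels(dim, center, round(truth$core_area_um2 / pa))
    plq_px <- .discPixels(dim, center, round(truth$area_um2 / pa))
    core_spec <- signal_level * (f * bases@compact + (1 - f) * bases@filamentous)
    fil_spec <- signal_level * bases@filamentous
    arr <- array(0, c(dim[1], dim[2], nb))
    .withSeed(deriveSeed(rng_seed, 1L), {
      for (b in seq_len(nb)) {
        plane <- matrix(0, dim[1], dim[2])
        plane[plq_px] <- fil_spec[b]
        plane[core_px] <- core_spec[b]
        arr[, , b] <- .noisy(plane, noise_sd)
      }
    })
    stack <- new("SpectralStack", data = arr, grid = bases@grid,
                 pixel_size_um = pixel_size_um)
  }
  tr <- truth
  tr$center_row <- center[1]; tr$center_col <- center[2]
  new("SyntheticScene", stack = stack, channels = channels,
      pixel_size_um = pixel_size_um, truth = tr,
      scene_id = as.character(truth$plaque_id))
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study conditions the analysis assumes: a
#' three-group design (PBS control, single and repeated peripheral LPS
#' challenge) with LPS groups shifted toward less compacted plaques,
#' plaque areas log-uniform inside the 100-2500 um^2 analysis gate,
#' microglial coverage declining with age, and a dystrophy channel whose
#' area is a planted linear function of corona, microglial and core areas
#' (strongly positive on the filamentous corona, moderately positive on
#' microglia, weakly negative on the compact core) with Gaussian noise
#' calibrated by default so the planted signal explains 60\% of dystrophy
#' variance.
#'
#' @param n_animals number of animals.
#' @param plaques_per_animal plaques per animal.
#' @param groups group labels, recycled over animals.
#' @param group_compaction_shift named per-group shift of mean compaction.
#' @param age_months animal ages, recycled over animals.
#' @param base_compaction cohort mean compaction for the reference group.
#' @param animal_sd between-animal SD of mean compaction.
#' @param plaque_sd within-animal SD of plaque compaction.
#' @param compaction_levels optional fixed compaction levels cycled over
#'   plaques (overrides the hierarchical compaction model).
#' @param area_range_um2 plaque area range (log-uniform sampling).
#' @param core_fraction_range range of the core area fraction.
#' @param beta_h,beta_i,beta_q planted dystrophy coefficients on corona,
#'   microglial and core area.
#' @param noise_sigma dystrophy residual SD (um^2); ignored when
#'   \code{target_r2} is given.
#' @param target_r2 calibrate \code{noise_sigma} so the planted linear
#'   predictor explains this fraction of dystrophy variance on the
#'   realized cohort; NULL to use \code{noise_sigma} directly.
#' @param microglia_base microglial coverage (Iba1 area / plaque area) at
#'   the reference age.
#' @param microglia_age_tau e-folding time (months) of the age-related
#'   coverage decline.
#' @param microglia_lsd log-scale SD of per-plaque coverage noise.
#' @param group_microglia_lsd optional named per-group override of
#'   \code{microglia_lsd} (used to widen one group's microglial spread).
#' @param pixel_size_um pixel edge length; the 0.5 um default makes the
#'   30/100/2500 um^2 gates exact integer pixel counts.
#' @param noise_sd additive image noise SD for rendered scenes.
#' @param qftaa_threshold threshold applied to the qFTAA channel.
#' @return A configuration list.
#' @export
cohortConfig <- function(n_animals = 10, plaques_per_animal = 20,
                         groups = c("PBS", "1xLPS", "4xLPS"),
                         group_compaction_shift =
                           c(PBS = 0, `1xLPS` = -0.10, `4xLPS` = -0.18),
                         age_months = 12, base_compaction = 0.55,
                         animal_sd = 0.05, plaque_sd = 0.10,
                         compaction_levels = NULL,
                         area_range_um2 = c(120, 2400),
                         core_fraction_range = c(0.10, 0.35),
                         beta_h = 0.45, beta_i = 0.25, beta_q = -0.15,
                         noise_sigma = 60, target_r2 = 0.60,
                         microglia_base = 0.5, microglia_age_tau = 18,
                         microglia_lsd = 0.12, group_microglia_lsd = NULL,
                         pixel_size_um = 0.5, noise_sd = 0.02,
                         qftaa_threshold = 0.1) {
  cfg <- as.list(environment())
  if (n_animals < 2 || plaques_per_animal < 1)
    .stopf("empty design: need >= 2 animals and >= 1 plaque per animal")
  miss <- setdiff(groups, names(group_compaction_shift))
  if (length(miss))
    .stopf("group_compaction_shift missing groups: %s",
           paste(miss, collapse = ", "))
  cfg
}

#' Simulate a plaque cohort with planted ground truth
#'
#' Draws the animal table (group, age, sex), per-plaque geometry and
#' compaction (shifted per group), microglial coverage, and the planted
#' dystrophy areas, and optionally renders per-animal image scenes. All
#' randomness flows from per-(animal, plaque) streams derived from the
#' master seed, so cohorts are bit-reproducible and partially
#' regenerable.
#'
#' @param config a list from \code{\link{cohortConfig}}.
#' @param seed integer master seed.
#' @param render \code{"none"} (truth only), \code{"channels"} (scalar
#'   channels per scene) or \code{"full"} (channels plus hyperspectral
#'   stacks).
#' @return A list with elements \code{truth} (a
#'   \linkS4class{CohortTruth}), \code{metadata} (the animal table) and
#'   \code{scenes} (list of per-animal \linkS4class{SyntheticScene}s, or
#'   NULL when \code{render = "none"}).
#' @examples
#' sim <- simulateCohort(cohortConfig(n_animals = 2, plaques_per_animal = 3),
#'                       seed = 1)
#' nrow(plaqueTruth(sim$truth))
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L,
                           render = c("none", "channels", "full")) {
  render <- match.arg(render)
  if (is.null(seed) || !is.finite(seed))
    .stopf("config error: a seed is required for simulation")
  seed <- as.integer(seed)
  cfg <- config
  pa <- cfg$pixel_size_um^2

  n_a <- cfg$n_animals
  animals <- data.frame(
    animal_id = sprintf("a%02d", seq_len(n_a)),
    group = rep_len(cfg$groups, n_a),
    age_months = rep_len(cfg$age_months, n_a),
    sex = rep_len(c("M", "F"), n_a),
    stringsAsFactors = FALSE)

  rows <- vector("list", n_a)
  for (a in seq_len(n_a)) {
    an <- animals[a, ]
    mu_a <- .withSeed(deriveSeed(seed, a), {
      cfg$base_compaction + cfg$group_compaction_shift[[an$group]] +
        stats::rnorm(1, 0, cfg$animal_sd)
    })
    lsd <- cfg$microglia_lsd
    if (!is.null(cfg$group_microglia_lsd) &&
        an$group %in% names(cfg$group_microglia_lsd))
      lsd <- cfg$group_microglia_lsd[[an$group]]
    cov_age <- cfg$microglia_base * exp(-(an$age_months - 3) / cfg$microglia_age_tau)
    np <- cfg$plaques_per_animal
    arl <- log(cfg$area_range_um2)
    dfa <- vector("list", np)
    for (p in seq_len(np)) {
      dfa[[p]] <- .withSeed(deriveSeed(seed, a, p), {
        area <- .pxArea(exp(stats::runif(1, arl[1], arl[2])), cfg$pixel_size_um)
        cf <- stats::runif(1, cfg$core_fraction_range[1],
                           cfg$core_fraction_range[2])
        core <- .pxArea(cf * area, cfg$pixel_size_um)
        f <- if (!is.null(cfg$compaction_levels)) {
          cfg$compaction_levels[(p - 1L) %% length(cfg$compaction_levels) + 1L]
        } else {
          min(max(stats::rnorm(1, mu_a, cfg$plaque_sd), 0), 1)
        }
        covg <- min(max(cov_age * exp(stats::rnorm(1, 0, lsd)), 0.05), 0.7)
        data.frame(
          plaque_id = sprintf("%s_p%03d", an$animal_id, p),
          animal_id = an$animal_id,
          core_radius_um = sqrt(core / pi),
          corona_radius_um = sqrt(area / pi),
          compaction_f = f, area_um2 = area, core_area_um2 = core,
          corona_area_um2 = area - core,
          iba1_area_um2 = .pxArea(covg * area, cfg$pixel_size_um),
          trem2_intensity = min(max(0.5 * exp(stats::rnorm(1, 0, 0.2)),
                                    0.05), 0.95),
          stringsAsFactors = FALSE)
      })
    }
    rows[[a]] <- do.call(rbind, dfa)
  }
  plq <- do.call(rbind, rows)

  eta <- cfg$beta_h * plq$corona_area_um2 + cfg$beta_i * plq$iba1_area_um2 +
    cfg$beta_q * plq$core_area_um2
  sigma <- if (!is.null(cfg$target_r2)) {
    if (cfg$target_r2 <= 0 || cfg$target_r2 > 1)
      .stopf("target_r2 must lie in (0, 1]")
    stats::sd(eta) * sqrt(1 / cfg$target_r2 - 1)
  } else cfg$noise_sigma
  eps <- numeric(nrow(plq))
  if (sigma > 0) {
    idx <- 0L
    for (a in seq_len(n_a)) for (p in seq_len(cfg$plaques_per_animal)) {
      idx <- idx + 1L
      eps[idx] <- .withSeed(deriveSeed(seed, a, p, 7L),
                            stats::rnorm(1, 0, sigma))
    }
  }
  plq$eta_um2 <- eta
  plq$app_area_um2 <- .pxArea(pmax(eta + eps, 0), cfg$pixel_size_um)

  truth <- new("CohortTruth", seed = seed, animals = animals, plaques = plq,
               beta = c(h = cfg$beta_h, i = cfg$beta_i, q = cfg$beta_q),
               noise_sigma = sigma,
               group_compaction_shift = unlist(cfg$group_compaction_shift),
               pixel_size_um = cfg$pixel_size_um, config = cfg)

  scenes <- NULL
  if (render != "none")
    scenes <- renderCohortScenes(truth, include_stack = render == "full")
  list(truth = truth, metadata = animals, scenes = scenes)
}

#' Render the image scenes of a simulated cohort
#'
#' Lays each animal's plaques out on a tile grid and renders one
#' \linkS4class{SyntheticScene} per animal.
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @param include_stack render hyperspectral stacks as well as channels.
#' @param bases basis spectra (default generated from the default grid).
#' @return Named list of \linkS4class{SyntheticScene}s, one per animal.
#' @export
renderCohortScenes <- function(truth, include_stack = TRUE,
                               bases = makeBasisSpectra()) {
  cfg <- truth@config
  px <- truth@pixel_size_um
  tile <- max(.tileEdge(truth@plaques, px))
  scenes <- list()
  for (a in seq_len(nrow(truth@animals))) {
    aid <- truth@animals$animal_id[a]
    tp <- truth@plaques[truth@plaques$animal_id == aid, , drop = FALSE]
    k <- nrow(tp)
    ncol_t <- ceiling(sqrt(k)); nrow_t <- ceiling(k / ncol_t)
    dims <- c(nrow_t, ncol_t) * tile
    ch_names <- c("qftaa", "hftaa", "abeta", "iba1", "app", "ptau", "nfl",
                  "cd68", "trem2")
    channels <- stats::setNames(
      lapply(ch_names, function(x) matrix(0, dims[1], dims[2])), ch_names)
    channels$congo_rgb <- array(.q16(0.5), c(dims[1], dims[2], 3))
    arr <- if (include_stack)
      array(0, c(dims[1], dims[2], nBands(bases@grid))) else NULL
    tp$center_row <- NA_real_; tp$center_col <- NA_real_
    for (p in seq_len(k)) {
      ti <- p - 1L
      r0 <- (ti %/% ncol_t) * tile; c0 <- (ti %% ncol_t) * tile
      pt <- renderPlaque(tp[p, ], bases, px,
                         noise_sd = cfg$noise_sd,
                         rng_seed = deriveSeed(truth@seed, a, p, 11L),
                         dim = c(tile, tile), include_stack = include_stack,
                         trem2_intensity = tp$trem2_intensity[p])
      rows <- r0 + seq_len(tile); cols <- c0 + seq_len(tile)
      for (nm in ch_names) channels[[nm]][rows, cols] <- pt@channels[[nm]]
      channels$congo_rgb[rows, cols, ] <- pt@channels$congo_rgb
      if (include_stack) arr[rows, cols, ] <- pt@stack@data
      tp$center_row[p] <- r0 + (tile + 1) / 2
      tp$center_col[p] <- c0 + (tile + 1) / 2
    }
    stack <- if (include_stack)
      new("SpectralStack", data = arr, grid = bases@grid, pixel_size_um = px)
    else NULL
    scenes[[aid]] <- new("SyntheticScene", stack = stack, channels = channels,
                         pixel_size_um = px, truth = tp, scene_id = aid)
  }
  scenes
}

#' Planted feature table of a simulated cohort
#'
#' The feature table the image pipeline recovers, computed directly from
#' the planted truth (no rendering): hFTAA area is the whole plaque area,
#' qFTAA area the core area when the core's compaction clears the qFTAA
#' channel threshold, the core intensity ratio equals the compaction
#' fraction, and co-stain areas are the planted ones. Useful as the exact
#' expectation for feature-extraction tests and for model experiments at
#' cohort scales where rendering every scene is unnecessary; the
#' colocalization fraction is geometry-dependent and is reported only by
#' the image route (NA here).
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @return A data.frame with one row per planted plaque.
#' @export
cohortFeatures <- function(truth) {
  stopifnot(is(truth, "CohortTruth"))
  plq <- truth@plaques
  an <- truth@animals[match(plq$animal_id, truth@animals$animal_id), ]
  qthr <- truth@config$qftaa_threshold
  qarea <- ifelse(plq$compaction_f >= qthr, plq$core_area_um2, 0)
  harea <- plq$area_um2
  n_app <- round(plq$app_area_um2 / truth@pixel_size_um^2)
  pa <- truth@pixel_size_um^2
  data.frame(
    plaque_id = plq$plaque_id, animal_id = plq$animal_id,
    group = an$group, age_months = an$age_months, sex = an$sex,
    plaque_area_um2 = harea, qftaa_area_um2 = qarea, hftaa_area_um2 = harea,
    area_ratio_qf_hf = qarea / harea,
    core_intensity_ratio_qf_hf = plq$compaction_f,
    iba1_area_um2 = plq$iba1_area_um2, app_area_um2 = plq$app_area_um2,
    iba1_area_norm = plq$iba1_area_um2 / harea,
    app_area_norm = plq$app_area_um2 / harea,
    ptau_area_norm = round(0.6 * n_app) * pa / harea,
    nfl_area_norm = round(0.4 * n_app) * pa / harea,
    cd68_area_norm = round(0.5 * round(plq$iba1_area_um2 / pa)) * pa / harea,
    trem2_area_norm = plq$iba1_area_um2 / harea,
    trem2_mean_intensity = plq$trem2_intensity,
    coloc_fraction = NA_real_,
    stringsAsFactors = FALSE)
}

#' Planted coefficient of determination
#'
#' The fraction of dystrophy-area variance explained by the planted
#' linear predictor over the realized plaque features:
#' \code{var(eta) / (var(eta) + noise_sigma^2)}. This is the oracle the
#' modeling stage is expected to recover.
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @return Fraction in \code{[0, 1]}.
#' @export
plantedR2 <- function(truth) {
  stopifnot(is(truth, "CohortTruth"))
  if (nrow(truth@plaques) < 2)
    .stopf("planted R^2 needs >= 2 plaques")
  v <- stats::var(truth@plaques$eta_um2)
  tot <- v + truth@noise_sigma^2
  if (tot == 0) .stopf("undefined R^2: zero total variance")
  v / tot
}

# ---- accessors / show ------------------------------------------------------

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SyntheticScene", function(object) object@pixel_size_um)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SpectralStack", function(object) object@pixel_size_um)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CohortTruth", function(object) object@pixel_size_um)

#' @rdname channelNames
#' @export
setMethod("channelNames", "SyntheticScene",
          function(object) names(object@channels))

#' @rdname getChannel
#' @export
setMethod("getChannel", "SyntheticScene", function(object, name) {
  if (!name %in% names(object@channels))
    .stopf("missing channel: '%s' (scene has: %s)", name,
           paste(names(object@channels), collapse = ", "))
  object@channels[[name]]
})

#' @rdname plaqueTruth
#' @export
setMethod("plaqueTruth", "SyntheticScene", function(object) object@truth)

#' @rdname plaqueTruth
#' @export
setMethod("plaqueTruth", "CohortTruth", function(object) object@plaques)

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf(
    "SyntheticScene '%s': %dx%d px (%.2f um/px), %d channels%s, %d plaques\n",
    object@scene_id, d[1], d[2], object@pixel_size_um,
    length(object@channels),
    if (is.null(object@stack)) "" else
      sprintf(" + %d-band stack", nBands(object@stack@grid)),
    nrow(object@truth)))
})

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf(
    "CohortTruth: %d animals, %d plaques (seed %d)\n",
    nrow(object@animals), nrow(object@plaques), object@seed))
  cat(sprintf("  groups: %s\n",
              paste(unique(object@animals$group), collapse = ", ")))
  cat(sprintf(
    "  planted beta (corona, iba1, core): %.3g, %.3g, %.3g; sigma %.3g um^2\n",
    object@beta[["h"]], object@beta[["i"]], object@beta[["q"]],
    object@noise_sigma))
})
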