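# Shared fixtures, all generated in code.

# Image with axis-aligned rectangles of exact pixel areas (um^2 at the
# given pixel size); returns list(image, masks) with one logical mask per
# rectangle. Rectangles are spaced so they never touch.
rectImage <- function(areas_um2, pixel_size_um = 0.5, gap_px = 6L) {
  pa <- pixel_size_um^2
  npx <- round(areas_um2 / pa)
  w <- vapply(npx, function(n) {
    k <- floor(sqrt(n))
    while (n %% k) k <- k - 1L
    k
  }, numeric(1))
  h <- npx / w
  height <- max(h) + 2 * gap_px
  width <- sum(w) + gap_px * (length(w) + 1L)
  img <- matrix(0, height, width)
  masks <- vector("list", length(npx))
  x0 <- gap_px
  for (i in seq_along(npx)) {
    rows <- gap_px + seq_len(h[i])
    cols <- x0 + seq_len(w[i])
    img[rows, cols] <- 1
    m <- matrix(FALSE, height, width)
    m[rows, cols] <- TRUE
    masks[[i]] <- m
    x0 <- x0 + w[i] + gap_px
  }
  list(image = img, masks = masks)
}

# Random logical mask of given shape and fill probability.
randomMask <- function(dim, p = 0.3) {
  matrix(stats::runif(prod(dim)) < p, dim[1], dim[2])
}

# Small noise-free cohort (exact planted areas survive thresholding).
noiseFreeCohort <- function(seed = 1, n_animals = 3, plaques_per_animal = 5,
                            ...) {
  simulateCohort(
    cohortConfig(n_animals = n_animals,
                 plaques_per_animal = plaques_per_animal,
                 noise_sd = 0, ...),
    seed = seed, render = "none")
}

defaultThresholds <- c(qftaa = 0.05, hftaa = 0.5, iba1 = 0.5, app = 0.5,
                       ptau = 0.5, nfl = 0.5, cd68 = 0.5, trem2 = 0.02)
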