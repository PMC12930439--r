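# Internal numeric and RNG helpers shared across modules.

# Snap intensities to the 16-bit unsigned grid used by scene TIFF storage,
# so that write -> read round trips are bit-identical. Values must lie in
# [0, 1]; callers clamp before snapping.
.q16 <- function(x) round(x * 65535) / 65535

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a reproducible child seed from a master seed
#'
#' Folds integer identifiers into a master seed with a multiplicative
#' congruential mix modulo 2^31 - 1, so that each (scene, animal, plaque)
#' combination owns an independent, reproducible RNG stream and cohorts can
#' be partially regenerated without disturbing other streams.
#'
#' @param master integer master seed.
#' @param ... further integer identifiers (e.g. animal index, plaque index).
#' @return A single integer in \code{[1, 2^31 - 2]}.
#' @export
deriveSeed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime; products stay exact in doubles
  s <- as.numeric(master) %% m
  for (v in unlist(list(...))) {
    s <- (s * 69069 + as.numeric(v) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Run expr under a local RNG state seeded with `seed`; restores the caller's
# RNG state afterwards so library functions never perturb user randomness.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Quantize an area in um^2 to a whole number of pixels.
.pxArea <- function(area_um2, pixel_size_um) {
  pa <- pixel_size_um^2
  round(area_um2 / pa) * pa
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
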