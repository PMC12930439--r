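---
title: "Methods: hyperspectral plaque morphotype analysis with planted ground truth"
author: "plaqueMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral plaque morphotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueMorph)
```

## The measurement problem

Amyloid plaques are not homogeneous deposits: a typical cored plaque has
a compacted center of tightly bundled fibrils surrounded by a corona of
loosely packed filamentous material. Two conformation-sensitive LCO dyes
resolve these states spectrally. qFTAA binds compacted fibrils and emits
with a blue peak near 502 nm; hFTAA binds filamentous and bundled
fibrils alike, with local emission maxima near 545 and 588 nm. Three
readouts of plaque compaction follow:

* the **502/588 nm emission ratio** of the mean core spectrum (dual
  stain), or the 545/588 nm ratio when only hFTAA is applied;
* the **qFTAA/hFTAA area ratio** of the thresholded dye channels;
* the **core intensity ratio** (mean qFTAA over mean hFTAA fluorescence
  in the core region).

Downstream, per-plaque morphometrics (normalized co-stain areas for
microglia and dystrophic neurites, colocalization fractions) feed a
support vector regression that asks which plaque property predicts
neuritic dystrophy, and an autoradiography module quantifies
amyloid-tracer binding as background-subtracted cortex-to-white-matter
ratios.

None of the original microscopy data are available, so the package
pairs every analysis stage with a synthetic scene generator that plants
known ground truth. Every quantitative claim the package makes is
checked against planted parameters, not against remembered numbers.

## The synthetic scene model

A plaque is a disc-shaped core of planted area inside an annular corona
(total area = "plaque area"). Core pixels carry the spectrum
`f * compact + (1 - f) * filamentous`, where `f` in [0, 1] is the
planted *compaction fraction*; corona pixels carry the filamentous
basis only. The basis spectra are sums of Gaussian bumps on the band
grid with peaks pinned to the bands nearest 502 nm (compact) and
545/588 nm (filamentous, 588 global); the bump widths (30 nm compact;
12 and 16 nm filamentous) and the 545 shoulder height (0.9) are free
parameters chosen so the filamentous basis shows the two required local
maxima with a clear dip between them — only the peak positions are
physically constrained.

Discs are *area-exact*: a planted area A at pixel size p covers exactly
`round(A / p^2)` pixels (those nearest the center, ties in raster
order). This removes pixelation slack from every area oracle: size
gates, planted-vs-measured comparisons, and the dystrophy-area oracle
are exact rather than "within a boundary ring".

Co-stain channels per plaque:

* **qFTAA** channel: intensity `f` over the core (no compact signal in
  a fully filamentous core); **hFTAA** and **amyloid antibody**: 1 over
  the whole plaque.
* **Congo Red**: RGB image, red over the core only, neutral gray
  elsewhere — the CIELAB a* detector sees exactly the core.
* **Iba1** (microglia): an annulus hugging the corona whose area is
  `coverage * plaque area`, with coverage declining exponentially in
  age (base 0.5 at the 3-month reference, e-folding 18 months,
  log-normal per-plaque noise, clamped to [0.05, 0.7] so the annulus
  always fits inside the 10 µm feature ROI).
* **APP** (neuritic dystrophy): a band of boutons straddling the plaque
  border whose total thresholded area is the planted linear model
  `beta_h * corona + beta_i * iba1 + beta_q * core + eps`, clipped at
  zero and quantized to whole pixels. Defaults
  `beta = (0.45, 0.25, -0.15)` plant the qualitative pattern of
  interest: filamentous amyloid strongly toxic, microglia moderately
  positive, compact core mildly protective. pTau and NfL are planted
  subsets (60 % / 40 %) of the APP band, CD68 a subset of the Iba1
  annulus, and Trem2 an intensity field on the annulus.

The dystrophy noise SD is, by default, *calibrated* on the realized
cohort so that the planted linear predictor explains exactly 60 % of
dystrophy variance (`target_r2 = 0.60`), matching the explained-variance
regime the modeling stage is expected to recover; `plantedR2()` returns
this quantity as the oracle.

Cohort structure: animals cycle through groups (default PBS, 1xLPS,
4xLPS — a control and two peripheral-inflammation challenges), sexes
alternate, and each group shifts the mean compaction (defaults 0,
-0.10, -0.18: inflammation decompacts plaques). Plaque areas are
log-uniform on 120–2400 µm² so every plaque passes the 100–2500 µm²
analysis gate; core fractions are uniform on 0.10–0.35. All randomness
derives from per-(animal, plaque) streams folded from the master seed,
so cohorts are bit-reproducible and partially regenerable.

What the generator deliberately does **not** emulate: irregular plaque
morphology (no in-scope metric depends on shape beyond area), Poisson
photon noise (additive truncated Gaussian only; no in-scope metric is
sensitive to the noise family at tested SNR), 3-D stacks (2-D
maximum-projection analysis throughout), vascular amyloid and
high-background regions (excluded manually in practice; the exclusion
mask input is still honored), and spatial autocorrelation between
neighbouring plaques (tiles are disjoint). Passing tests therefore
demonstrate correctness of the measurement chain, not robustness to
every real-tissue artifact.

## Spectral module

The band grid is 470 nm + k·10.7 nm, 22 bands (band centers 502.1,
544.9 and 587.7 nm sit within 0.3 nm of the readout wavelengths, which
is why nearest-band lookup is used instead of interpolation; ties break
toward the lower wavelength). Per plaque, three core ROIs are averaged
pixel-wise, the three ROI means averaged, and the result max-normalized
— normalization applies to the averaged spectrum, not per ROI, so the
ratio readout is invariant to any positive scaling of the raw stack.

ROI placement is automated (the manual step is not reproducible): the
three centers are the deepest pixel of the core's distance transform
followed by farthest-point sampling among pixels where a disc of the
ROI radius (default 1.5 µm) still fits; ties break in raster order. If
the core is too small to erode, the radius collapses gracefully down to
single-pixel ROIs — three ROIs are always produced for a non-empty
core. Degenerate inputs (empty ROI, all-zero spectrum, zero intensity
at the denominator band) raise typed errors rather than NaNs.

Per-animal summaries flag animals contributing fewer than 35 plaques
(20 in single-stain mode) rather than dropping them.

## Segmentation and gating

Plaque detection is a fixed threshold plus connected components.
Connectivity defaults to 8-neighbour (4-neighbour available); labels
are assigned in raster-scan order of each component's first pixel, so
label maps are deterministic. The plaque-load filter removes components
below 30 µm²; the per-plaque analysis gate keeps areas in the *closed*
interval [100, 2500] µm² — "smaller than 100" and "bigger than 2500"
are read as strict exclusions, so boundary plaques are retained, and
the default 0.5 µm pixel makes all three bounds exact integer pixel
counts (120, 400, 10 000). Congo Red detection converts sRGB to CIELAB
(D65) and thresholds a* > 0; the threshold is configurable for stained
tissue whose background is not neutral. Manual curation is replaced by
the exclusion-mask input; optional percentile rescaling stands in for
interactive gamma adjustment and is off by default on synthetic data.

## Feature extraction

Co-stain areas are measured inside the plaque mask dilated by 10 µm
(configurable) — wide enough, given the generator's geometry caps, to
contain the whole microglial annulus and dystrophy band. The plaque
mask for normalization and colocalization is the thresholded hFTAA
channel united with the qFTAA core, so the whole plaque is the
denominator. Colocalization is the plain set-intersection fraction in
2-D (the 3-D tool it stands in for applies the same formula on
maximum-intensity projections). Overlap-vs-size curves take bin edges
as configuration; log-spaced edges over the gate are the sensible
default since no canonical edges exist.

## Dystrophy model

Predictors are sex, age, Iba1 area, qFTAA area, hFTAA area and the core
qF/hF ratio; the response is APP area. Splits are at the *animal*
level (80:20 by default), cross-validation folds are grouped by animal
(the split philosophy extended to CV, which the protocol leaves open),
and standardization statistics come from training rows only — a
no-leakage property asserted by recomputation in the tests. The SVR is
radial-kernel epsilon-regression; since kernel and hyperparameters are
not specified by the protocol, a small logarithmic grid (cost 1/10/100,
gamma 0.3/1/3 per predictor count, epsilon 0.1 on the standardized
response) is searched by grouped 5-fold CV and the selection is logged
in the result object. A constant response short-circuits to the mean
predictor instead of failing.

Feature importance is permutation importance on the test partition
(columns permuted within animals, mean R² drop over permutations), with
the marginal-effect sign taken from the slope of the partial-dependence
curve — this reproduces signed importance bars in kind. The transfer
test applies a fitted model to groups never seen in training, erroring
on any overlap.

Model-scale experiments (the ~2,750-plaque recovery and the 20-seed
transfer protocol) run on the generator's planted feature table rather
than rendering thousands of tiles; the rendered-image route is proven
exactly equal to the planted table (areas and ratios) on smaller
cohorts, so the shortcut changes nothing but runtime. The planted table
reports no colocalization fraction (geometry-dependent; image route
only).

The effect-leverage regression is ordinary least squares on an
optionally log10- or log10(x+1)-transformed response. For each
predictor the leverage pair is (residual of X on the other predictors +
mean X, residual of Y on the other predictors + mean Y); the pairs are
therefore centered at the data means exactly, and the least-squares
line through them has the fitted coefficient as slope.

## Autoradiography

`roiRatio` is `(mean(cortex) - background) / (mean(reference) -
background)` with typed errors for empty, overlapping, or
below-background ROIs. The simulator binds tracer to compact amyloid
only: cortex intensity is `baseline * (1 + gain * total core area)`,
reference stays at baseline, so at zero noise `(ratio - 1)` is exactly
linear in planted compact area and zero compact area gives ratio 1.

The insensitivity property is tested on cohorts in which core and
corona areas vary *independently* across animals. Holding total amyloid
fixed while varying compaction — the more obvious design — makes corona
area a deterministic complement of core area, so the filamentous
regression would trivially mirror the compact one with opposite sign;
independent variation is the design under which "tracks compact, not
filamentous amyloid" is actually falsifiable.

## Numerical and storage choices

Scene intensities live in [0, 1] and are snapped to the 16-bit integer
grid at generation time; scenes are stored as 16-bit TIFF (multi-page
for the spectral stack), making write-read round trips bit-identical
and two runs of the same configuration byte-identical. Feature tables
are CSV with a schema-version header carrying the configuration hash
(MD5 of the canonical config deparse); numeric columns are written with
17 significant digits, round-tripping below 1e-12 relative. Model
metadata is JSON without timestamps, so reproducibility is testable by
file comparison.

## Problem sizes

The test and acceptance workloads use: 200 plaques across 10 animals
for spectral recovery (rendered at SNR 10); 48 animals x 58 plaques
(~2,750) for the planted-R² SVR recovery; 20 seeds of 16 animals x 35
plaques for the transfer protocol; 24 animals x 20 seeds for the
autoradiography regressions; and a 10 x 20 demo cohort for end-to-end
determinism. These sizes were chosen to match the cohort scales the
analysis is designed for while keeping a full verification run on a
laptop-class single core.

## Known limitations

Compaction enters dystrophy only through areas, so the core intensity
ratio is a near-null predictor by construction; plaques are radially
symmetric; group effects on microglial coverage are limited to variance
scaling; and the human-cohort protocol is represented by its group
structure (train on three groups, transfer to a fourth), not by any
attempt to emulate human neuropathology.
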