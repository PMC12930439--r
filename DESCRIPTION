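Package: plaqueMorph
Title: Hyperspectral Amyloid Plaque Morphotype Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies amyloid plaque morphotypes from hyperspectral
    fluorescence microscopy of conformation-sensitive luminescent
    conjugated oligothiophene (LCO) dyes. Provides per-plaque emission
    spectrum ratiometry (502/588 nm and 545/588 nm), plaque segmentation
    with size gating, CIELAB-based Congo Red detection, per-plaque
    morphometrics and colocalization, support vector regression of
    neuritic dystrophy with animal-grouped cross-validation and
    permutation feature importance, effect-leverage linear regression,
    and autoradiography ratio quantification. A synthetic scene
    generator with planted ground truth (compact core / filamentous
    corona plaques, microglial coverage, dystrophy channel) makes every
    stage verifiable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    e1071,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: Software, CellBiology, Visualization, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
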