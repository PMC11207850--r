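Package: mofdiff
Title: Single-Crystal Guest-Molecule Diffusion Imaging and Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying guest-molecule transport in single porous
    crystals (metal-organic frameworks) from time-lapse colour microscopy.
    Provides a finite-difference simulator of three-dimensional diffusion
    into and out of a faceted crystal with Beer-Lambert optical rendering
    of microscopy-like RGB frames; a histogram-based image pipeline
    (reference subtraction, red-channel extraction, mean-intensity traces);
    release-kinetics fitting with FRAP-style and mean-square-displacement
    diffusion-coefficient estimators; and design calculations for
    colorimetric MOF sensing (loading capacity, pore-window accessibility,
    uptake rates, saturation ordering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
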