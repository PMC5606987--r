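Package: cdslm
Title: Cleared-Tissue Light-Sheet Autofocus, HiLo Reconstruction and Stereology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for cleared-tissue digital scanned
    light-sheet microscopy (C-DSLM). Provides a virtual light-sheet
    microscope that renders defocused uniform/structured image pairs from
    a specimen volume, a Gaussian-beam sheet model and a refractive-index
    profile, with seeded Poisson and read noise and known ground-truth
    focus offsets; FFT pattern-frequency estimation with mean-squared-error
    scoring and Shannon entropy of the discrete cosine transform (SE-DCT)
    as focus metrics; coarse-to-fine autofocus, excitation sweep-limit
    determination, calibration-curve construction and interpolation, and
    calibrated versus constant-offset volumetric scan modes; HiLo
    structured-illumination reconstruction with theoretical and automatic
    selection of the fusion weight; mean-linear-intercept stereology in
    two and three dimensions and threshold/connected-component fluorescent
    cell counting; and multi-page TIFF stack I/O with plain-text sidecar
    metadata and a TeraStitcher-compatible tiled directory writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
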