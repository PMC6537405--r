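Package: cellfate3d
Title: Pixel-Ratio Viability and Proliferation Scoring for 3D Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch image-analysis pipeline for image-based cell-fate assays in 3D
    culture. Converts directories of single-plane multi-channel fluorescence TIFF
    z-stacks into per-treatment viability and proliferation scores: Gaussian
    flat-field illumination correction, automatic foreground thresholding by Yen's
    maximum-correlation criterion estimated from central z-slices, a ten-fold
    signal-absence rule for stacks devoid of biological signal, dual death-marker
    (ethidium homodimer / apopxin) overlap subtraction, vehicle (DMSO)
    normalization, co-culture GFP channel deconvolution, and Holm-Sidak corrected
    Welch tests between conditions. Includes a seeded synthetic scene generator
    that renders ground-truthed multi-channel stacks (defocus halos, vignetting,
    detector noise) so the entire pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
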