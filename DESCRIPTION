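Package: beatsync
Title: Retrospective Synchronization and 4D Reconstruction of Beating-Heart
    Light-Sheet Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns asynchronously acquired per-depth time-lapse image stacks
    (Z-movies) of a beating zebrafish heart into a time-resolved 3D
    reconstruction by retrospective cardiac gating: per-movie cycle-length
    estimation and cross-movie phase alignment driven by sum-of-squared-
    differences image similarity, with a triple-movie comparison that guards
    against local optima. Ships the surrounding quantitative toolkit --
    point-spread-function FWHM calibration from bead volumes, watershed
    nuclei segmentation and nearest-neighbour tracking, and single-cell
    contractility metrics (velocity, pairwise distance, surface-area-to-volume
    ratio, mesh export) -- together with a synthetic beating-heart phantom
    generator that provides full ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    EBImage,
    minpack.lm,
    parallel,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
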