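Package: microgliaMorph
Title: Microglia Morphometry, Morphology Classification and Phagocytosis
    Quantification from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify microglial cells in two-channel fluorescence
    microscopy images and time-lapses. Provides segmentation of a cytoplasmic
    reporter channel into label masks (anisotropic diffusion smoothing,
    relative thresholding, connected components, size and skeleton-length
    filters, scripted mask edits, overlap-based tracking), per-cell
    morphometric feature extraction (area, perimeter, geodesic diameter,
    skeleton statistics, and ten derived shape ratios), morphology
    classification into seven classes by a supervised two-dimensional
    embedding followed by density clustering and per-cluster majority voting
    with k-fold cross-validation, and phagocytosis quantification from a
    nucleic-acid-stain channel (auto-thresholding, particle containment,
    engulfment confirmation across time, phagocytosis index). A synthetic
    field generator renders parameterized cell archetypes and debris
    particles with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
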