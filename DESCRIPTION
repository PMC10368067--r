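Package: octparticles
Title: Particle Detection and 3-D Spatial Analysis for Retinal OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies inflammatory particles in the vitreous of murine
    retinal optical coherence tomography (OCT) volumes. Detects bright
    particles in B-scans with a marked point process of non-overlapping
    vertical rectangles fitted by energy minimization, extracts the retina
    surface with a classical multi-step image-processing pipeline,
    reconstructs and counts particles in 3-D via connected components,
    measures particle-to-surface distances with a Euclidean distance
    transform, and characterizes the spatial distribution of particle
    centroids with an edge-corrected 3-D Ripley K-function against a
    complete-spatial-randomness reference. Includes a synthetic OCT phantom
    generator with full ground truth so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    tiff,
    png,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
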