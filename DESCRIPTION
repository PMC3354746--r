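Package: mammoskin
Title: Breast MRI Skin Segmentation and Skin-Aware Biomechanical Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-stage segmentation of the skin layer in T2-weighted breast
    magnetic resonance volumes: breast/axial-zone separation, edge-preserving
    curvature-flow smoothing, low-intensity background clearing, two-stage
    C-means intensity clustering, geometric skin extraction with a metric
    depth limit in the nipple region, iterative artifact filters, and a 3D
    skin closure that leaves no internal tissue exposed to background. Also
    provides fat/fibroglandular tissue segmentation of the skin-free volume,
    a synthetic breast phantom generator with ground-truth labels, overlap
    metrics, the neo-Hookean strain-energy form with tissue presets, and the
    committed-error metric for plate reaction forces under mammographic
    compression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
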