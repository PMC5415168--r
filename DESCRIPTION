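Package: rootct
Title: Segmentation and Architecture Analysis of Plant Root Systems in X-Ray Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying, extracting and measuring plant root
    systems in 3D X-ray micro-computed tomography volumes of soil. Provides
    inter-scan grey-value normalization by histogram peak matching, stitching
    of overlapping sequential scans, partial-volume-aware segmentation
    (two-fold upsampling, 2D Sobel edge masking with isodata auto-threshold,
    bilevel grey thresholding, 3D median and erosion filters, seeded
    connectivity extraction), 3D skeletonization with tip/slab/junction
    classification, branch decomposition, root length density depth profiles
    and 3D maps, and batch branch-angle measurement. Includes a synthetic
    soil-root phantom generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
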