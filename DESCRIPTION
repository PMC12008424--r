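Package: anchorreg
Title: Anchor-Point Based Non-Rigid Image Registration for Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers microscopy images to predefined structural models by
    matching anchor points. A rough matching stage filters periodic point
    clouds with a neighbour-distance vote rule, places the model by
    brute-force translation search and pairs points by gated nearest
    neighbours; a fine matching stage estimates a planar homography robustly
    by least-median-of-squares and reconstructs anchor coordinates on an
    absolute scale. Includes keypoint and square-corner extraction from
    images, perspective rectification of distorted scans, unit-cell feature
    encoding for cross-frame matching, registration accuracy metrics (MAE,
    OKS-based recall) and a Monte-Carlo validation sweep of estimation
    accuracy under detection noise.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
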