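Package: vertseg
Title: Level-Set Segmentation and Morphometry for Vertebral CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting bone regions in 2-D CT-like slices of the
    lumbar spine and for the downstream spinal morphometry and clinical
    efficacy summaries used in lumbar disc herniation studies. Implements a
    neighborhood-fused exponential contrast enhancement, Chan-Vese (global
    two-phase) and local-binary-fitting (intensity-inhomogeneity-robust)
    level-set active contours, an iterative frame-fusion bone-region
    prediction pipeline over sequential slices with suture-band noise
    suppression, a seeded synthetic vertebra phantom generator with ground
    truth, and morphometry operations (protrusion to canal area ratio, disc
    height, vertebral slippage) plus efficacy grading and group-comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
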