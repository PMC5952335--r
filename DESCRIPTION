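Package: trackmargin
Title: Auto-Adaptive Tracking Margins for MLC-Tracked Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time auto-adaptive margin generation for multileaf-collimator
    (MLC) tracked radiotherapy. Estimates the statistics of aperture-versus-target
    positioning errors on-line with a Gaussian kernel density estimator over a
    cyclic sample buffer, translates them through a penumbra-aware convolution
    dose model into per-side, per-axis tracking margins at a chosen coverage
    level, and applies those margins to MLC segments by raster dilation, contour
    extraction and sub-leaf averaged leaf fitting. Includes a virtual-MLC
    delivery simulator (breathing-like motion synthesis, sensing latency,
    first-order machine response, target-frame dose accumulation) and dose-area
    histogram analysis for evaluating coverage recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
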