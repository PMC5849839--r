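Package: cutoutof
Title: Electron Cutout Output Factor Prediction by Annular-Kernel Convolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts relative output factors for arbitrarily shaped electron
    cutouts from a small set of circular-cutout measurements. Measured
    output-factor curves are fitted with a monotone interpolant, decomposed
    into annular output factors, and turned into a circularly symmetric 2D
    convolution kernel; convolving the kernel with a rasterized aperture
    yields the full 2D cutout-output-factor map, the recommended measurement
    point, and the output factor at any point. Includes inverse-square
    extension of curves to extended source-to-surface distances, gamma-index
    comparison of planar distributions, the perimeter-squared-over-area
    shape-complexity measure, and seeded synthetic generators for curves,
    cutout shapes, and noisy film-like distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mgcv,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
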