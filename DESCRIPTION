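Package: blurtex
Title: Blur-Invariant Texture Classification via Blur Equalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Makes texture descriptors invariant to image blur by equalizing
    every image's blur level before feature extraction: each image is
    recursively convolved with a small Gaussian kernel until a no-reference
    blur measure reaches a preset threshold, so that classifiers trained on
    sharp images generalize to blurred ones. Implements three no-reference
    blur measures (Marziliano edge-width, Crete perceptual blur, and a simple
    neighbour-contrast measure), five classical texture descriptors
    (multi-resolution uniform LBP, edge-based LBP, multi-fractal spectrum,
    edge co-occurrence matrix, local phase quantization), Gaussian, averaging
    and median degradation simulators, a seeded generator of class-structured
    synthetic textures, and a train-clean/evaluate-blurred experimental
    harness with linear support-vector classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    e1071,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
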