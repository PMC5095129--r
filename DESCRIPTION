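Package: samorph
Title: Morphometrics and QTL Mapping for Shoot Apical Meristem Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of shoot apical meristem (SAM) morphology
    from two-dimensional median-section contours. Models the SAM as a
    paraboloid of revolution to derive eight shape and size estimators from
    height and radius; normalizes digitized open contours (arc-length
    resampling to pseudo-landmarks, generalized Procrustes alignment) and
    extracts discrete cosine transform harmonic shape descriptors with
    principal component analysis; and performs single-QTL genome scans for
    advanced backcross (BC2S3) populations via a hidden Markov model of
    genotype probabilities, Haley-Knott regression, permutation significance
    thresholds, and Bayes credible intervals. Includes a synthetic-data
    generator for crosses, contours, and diverse-taxa contour panels so the
    full pipeline can be exercised and validated without micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
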