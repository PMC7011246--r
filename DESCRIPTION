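Package: radiotex
Title: MRI Radiomics Texture Pipeline for Small-Animal Tumor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a canonical 152-feature radiomics vector (first-order
    statistics, gray-level co-occurrence and run-length matrices, local binary
    patterns, fractal and shape descriptors, computed on the base image, its
    Sobel gradient, four single-level Haar wavelet sub-bands, and a global
    histogram of oriented gradients) from 2D tumor regions of interest,
    removes redundant features by pairwise correlation, selects a
    discriminative subset with an exhaustive-search RBF-SVM under
    leave-one-out cross-validation, and quantifies univariate associations of
    features with group labels, survival, and histology markers. Includes a
    synthetic-cohort generator producing two-group Gaussian-random-field
    tumor phantoms with texture-linked survival and histology markers so the
    full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
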