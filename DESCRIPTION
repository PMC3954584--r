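Package: dcttriage
Title: Whole-Image Breast Image Triage from Discrete Cosine Transform Band Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies whole mammographic images as normal or suspicious from
    moment features of dyadic L-shaped bands of the image's discrete cosine
    transform. Provides image loading and artifact masking, geometry
    standardization to a canonical 200 micrometre 1024x1024 frame, the
    41-feature band-moment extractor, leave-one-out k-nearest-neighbour
    classification with four vote-weighting variants and exhaustive small
    feature-subset search, a histogram naive Bayes classifier with
    sensitivity-first threshold selection, ROC utilities including the DeLong
    comparison of correlated ROC curves, and a seeded phantom-image generator
    with class-dependent power-law texture for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
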