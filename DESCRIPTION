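Package: ipclkit
Title: Patch-Based CNN-SVM Recognition of Microvascular Morphological Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing intraepithelial papillary capillary loop
    (IPCL) morphological types (A, B1, B2_B3) in annotated narrow-band-imaging
    style endoscopy images. Implements greedy constrained patch tiling of
    labeled regions, image-level rescaling/rotation/flip augmentation, a small
    convolutional network (NBI-Net) trained as a feature extractor, a
    one-against-one soft-margin SVM head over network or classical texture
    features (dense-SIFT bag-of-words PHOW, uniform-58 LBP, PHOG), Gaussian
    weighted voting to synthesize full-image class overlays, and case-level
    cross-validated evaluation. Includes a deterministic synthetic-fixture
    generator emulating the structure of annotated endoscopy datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    Rcpp,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
RoxygenNote: 7.3.3
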