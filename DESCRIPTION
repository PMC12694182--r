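Package: holostain
Title: Virtual Staining of Off-Axis Digital Holograms for Rare Tumor-Cell
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and learned virtual staining of off-axis
    digital holograms of liquid-cytology smears. Generates synthetic fields of
    PBMC-like and tumor-like (HCT116-like) cells with paired fluorescence,
    reconstructs quantitative phase by angular-spectrum propagation with
    numerical autofocus and reference-based aberration correction, builds
    phase plus orthogonal phase-gradient network inputs and fluorescence-derived
    stain targets, trains a U-net with mean-absolute-error loss and Adam, and
    evaluates staining quality at image level (SSIM) and cell level
    (precision, recall, F1, accuracy).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    tiff,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    dplyr,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
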