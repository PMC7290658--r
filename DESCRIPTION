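Package: myofuse
Title: Quantification of Myotube Fusion from Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify myogenic differentiation and myoblast fusion
    from two-channel fluorescence microscopy (DAPI nuclei, embryonic myosin
    heavy chain cytoplasm). Implements nuclei segmentation via rolling-ball
    background subtraction, Otsu thresholding, binary cleanup and
    connected-component particle analysis; assignment of nuclear centroids to
    myotube regions of interest; fusion phenotyping metrics (nuclei density,
    differentiation index, nuclei-per-myotube distributions and size-class
    fractions) with the associated two-group statistics; and classification of
    genes regulated in opposing directions across two differential-expression
    contrasts after Benjamini-Hochberg correction. A synthetic-data module
    simulates ground-truth fields of multinucleated myotubes and mononucleated
    cells, renders them to two-channel images, and generates two-contrast
    differential-expression tables with planted opposing regulation, so the
    whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
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
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
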