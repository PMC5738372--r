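Package: dermoct
Title: Optical and Textural Analysis of Skin Optical Coherence Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for quantitative analysis of dermatological optical
    coherence tomography (OCT) B-scans. Segments skin images into epidermis
    and dermis by tracing the dermal-epidermal junction as a minimum-cost
    path over an attenuation-derived cost map, extracts an optical feature
    (the depth attenuation coefficient fitted by Levenberg-Marquardt
    nonlinear least squares) together with first-order, gray-level
    co-occurrence (GLCM) and gray-level run-length (GLRLM) texture
    statistics from layer and lesion regions of interest, selects features
    by principal-component loadings, and classifies lesion versus healthy
    regions with a repeated, stratified cross-validated classifier suite.
    Includes a synthetic OCT generator (two-layer skin with depth-exponential
    decay, correlated multiplicative speckle and insertable lesions) so the
    whole pipeline is testable without clinical data, plus body-site
    comparison statistics (interval summaries, one-way ANOVA, pairwise
    t-test maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    tools,
    mgcv,
    minpack.lm,
    e1071,
    MASS,
    class,
    nnet,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
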