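Package: cfichill
Title: Dual-Band Chlorophyll Fluorescence Image Analysis for Chilling
    Injury Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting chilling injury in green produce from
    dual-band (675 nm / 750 nm) chlorophyll fluorescence images: a
    synthetic scene generator for labelled dual-band image pairs,
    unimodal-histogram (Rosin) fruit segmentation, vignetting correction
    by bi-dimensional empirical mode decomposition and image
    reconstruction, extraction of a 167-dimensional per-band texture and
    intensity feature set (Haralick, uniform LBP, Gabor, basic intensity,
    Hu moments), replicated linear soft-margin SVM evaluation with
    cross-validated regularization, neighborhood component analysis
    feature ranking with incremental subset evaluation, and
    ANOVA/Fisher-LSD comparison of classifier accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    EBImage,
    e1071,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
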