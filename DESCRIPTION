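Package: gdmnir
Title: Chemometric Classification of Serum NIR Spectra for Gestational
    Diabetes Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-class chemometric modelling of near-infrared
    (NIR) serum spectra, built around the workflow used to screen for
    gestational diabetes mellitus (GDM): spectral containers with
    replicate-aware metadata, composable mathematical pretreatments
    (Savitzky-Golay smoothing and derivatives, SNV, weighted
    least-squares baseline removal, 2-norm normalization, centering and
    autoscaling), single-block PLS-LDA and two-block sequential
    orthogonalized PLS-LDA (SO-PLS-LDA) classifiers, a repeated double
    cross-validation engine with inner-loop latent-variable selection,
    classification figures of merit (specificity, sensitivity,
    non-error rate, AUROC) with ROC vertical averaging, variable
    importance in projection (VIP) with contiguous spectral-interval
    reporting, and a synthetic cohort generator that emulates
    two-class serum NIR spectra with region-dependent noise and the
    clinical covariate structure of a pregnancy cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Metabolomics, Proteomics, Software
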