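#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats approx lm.wfit poly rbinom rnorm sd var
#' @importFrom utils head read.csv write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib gdmnir, .registration = TRUE
NULL

#' SpectrumSet: a replicate-aware container for NIR spectra
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay `"intensity"` holding one spectral variable per row and one
#' record (an instrumental replicate of a subject's sample) per column.
#' `rowData()` carries the wavenumber axis in cm-1, stored strictly
#' descending (instrument convention, 10,500 -> 4000). `colData()` carries
#' `record_id`, `subject_id`, `replicate` and the binary class `label`
#' (1 = GDM, 0 = NGT). The unit of the intensities -- `"reflectance"`
#' (transflectance fraction, all values > 0) or `"absorbance"` (AU) -- lives
#' in `metadata()$unit`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [SpectrumSet()], [reflectanceToAbsorbance()],
#'   [averageReplicates()], [extractRange()]
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment")

.validSpectrumSet <- function(object) {
    msg <- character()
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!"wavenumber" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a 'wavenumber' column")
    if (!all(c("record_id", "subject_id", "replicate", "label") %in%
             colnames(cd)))
        msg <- c(msg,
            "colData must contain record_id, subject_id, replicate, label")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is missing")
    unit <- S4Vectors::metadata(object)$unit
    if (is.null(unit) || !unit %in% c("reflectance", "absorbance"))
        msg <- c(msg, "metadata()$unit must be 'reflectance' or 'absorbance'")
    if (length(msg))
        return(msg)
    wn <- rd$wavenumber
    if (length(wn) > 1L && any(diff(wn) >= 0))
        msg <- c(msg, "wavenumbers must be strictly descending")
    lab <- cd$label
    if (!all(lab %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0 (NGT) or 1 (GDM)")
    if (anyDuplicated(paste(cd$subject_id, cd$replicate, sep = "\r")))
        msg <- c(msg, "duplicated (subject_id, replicate) pairs")
    bad <- tapply(lab, cd$subject_id, function(v) length(unique(v)) > 1L)
    if (any(bad))
        msg <- c(msg, paste0("conflicting labels within subject(s): ",
                 paste(names(bad)[bad], collapse = ", ")))
    if (identical(unit, "reflectance") &&
        any(SummarizedExperiment::assay(object, "intensity") <= 0))
        msg <- c(msg, "reflectance values must be strictly positive")
    if (length(msg)) msg else TRUE
}
setValidity("SpectrumSet", .validSpectrumSet)

#' PLS1 regression model
#'
#' Single-response partial least squares model fitted by NIPALS with
#' X-deflation. The scores satisfy `T = Xc R` on the centered training
#' matrix, the regression coefficients `b = R q`, and predictions may be
#' computed equivalently through the scores or the coefficients.
#'
#' @slot weights deflated-X weight matrix W (variables x A)
#' @slot rotation weight matrix R mapping centered X to scores, T = Xc R
#' @slot scores training score matrix T (rows x A)
#' @slot xLoadings loading matrix P (variables x A)
#' @slot yLoadings y-loading vector q (length A)
#' @slot coef regression coefficient vector b = R q (length variables)
#' @slot coefPath coefficient matrix, column a = coefficients using 1..a
#'   components (variables x A)
#' @slot xMeans,yMean training centering parameters
#' @slot ncomp number of components actually extracted
#' @export
setClass("PLSModel", representation(
    weights = "matrix", rotation = "matrix", scores = "matrix",
    xLoadings = "matrix", yLoadings = "numeric", coef = "numeric",
    coefPath = "matrix", xMeans = "numeric", yMean = "numeric",
    ncomp = "integer"))

#' One-dimensional LDA decision threshold on predicted responses
#'
#' @slot threshold decision threshold on the predicted-response scale
#' @slot orientation `"gdm_above"` if the GDM training mean lies above the
#'   threshold, `"gdm_below"` otherwise
#' @slot means class means of the predicted responses, `c(m0, m1)`
#' @slot pooledVar pooled within-class variance
#' @slot priors class priors `c(pi0, pi1)`, summing to 1
#' @export
setClass("LDAThreshold", representation(
    threshold = "numeric", orientation = "character", means = "numeric",
    pooledVar = "numeric", priors = "numeric"))

setValidity("LDAThreshold", function(object) {
    if (!object@orientation %in% c("gdm_above", "gdm_below"))
        return("orientation must be 'gdm_above' or 'gdm_below'")
    if (abs(sum(object@priors) - 1) > 1e-8)
        return("priors must sum to 1")
    TRUE
})

#' Sequential orthogonalized two-block PLS model
#'
#' @slot block1 PLS model on the first predictor block
#' @slot block2 PLS model on the orthogonalized second block (residual fit);
#'   may have 0 components
#' @slot x2Means centering means of the raw second block
#' @slot orthCoef projection coefficients G = (T1'T1)^-1 T1' X2c used to
#'   orthogonalize new second-block data through predicted block-1 scores
#' @slot fitted training-set combined predicted response
#' @slot blockOrder character vector naming the block order used
#' @export
setClass("SOPLSModel", representation(
    block1 = "PLSModel", block2 = "ANY", x2Means = "numeric",
    orthCoef = "matrix", fitted = "numeric", blockOrder = "character"))

#' Result of a repeated double cross-validation run
#'
#' @slot metrics data.frame with one row per repetition: Sp, Se, NER, AUROC
#' @slot scores list (per repetition) of pooled outer-fold predicted
#'   responses, in cohort order
#' @slot labels list (per repetition) of pooled outer-fold predicted labels
#' @slot truth the observed class labels
#' @slot log data.frame with one row per repetition x outer fold recording
#'   the selected hyperparameters
#' @slot vipSum running sum of per-outer-model VIP vectors (or NULL)
#' @slot vipModels number of models contributing to `vipSum`
#' @slot config the `DCVConfig` used
#' @export
setClass("DCVResult", representation(
    metrics = "data.frame", scores = "list", labels = "list",
    truth = "integer", log = "data.frame", vipSum = "ANY",
    vipModels = "integer", config = "ANY"))
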