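#' @rdname SpectrumSet
#' @param x a `SpectrumSet`
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectrumSet
#' @export
setGeneric("intensityMat", function(x) standardGeneric("intensityMat"))

#' @rdname SpectrumSet
#' @export
setGeneric("unitType", function(x) standardGeneric("unitType"))

#' @rdname SpectrumSet
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname SpectrumSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Convert transflectance intensities to absorbance
#'
#' Replaces every reflectance fraction R by A = log10(1/R) and flags the set
#' as absorbance. The inverse map is R = 10^(-A).
#'
#' @param s a `SpectrumSet` with `unitType(s) == "reflectance"`
#' @return a `SpectrumSet` in absorbance units
#' @export
setGeneric("reflectanceToAbsorbance",
    function(s) standardGeneric("reflectanceToAbsorbance"))

#' Average instrumental replicates per subject
#'
#' Collapses the replicate records of each subject to their arithmetic mean,
#' preserving the class label and recording the replicate count per subject
#' in `colData()$n_replicates`. A warning is raised for subjects whose
#' replicate count differs from `expected` (the acquisition protocol records
#' five instrumental replicates per sample).
#'
#' @param s a `SpectrumSet`
#' @param expected expected replicate count per subject (default 5)
#' @return a subject-level `SpectrumSet`, one record per subject
#' @export
setGeneric("averageReplicates",
    function(s, expected = 5L) standardGeneric("averageReplicates"))

#' Extract a named wavenumber range
#'
#' Keeps the spectral variables whose wavenumber lies within the closed
#' interval of the requested range. Bounds are closed on both ends, so a
#' boundary wavenumber shared by adjacent ranges (7600, 5100 on grids that
#' contain them) belongs to both.
#'
#' @param s a `SpectrumSet`
#' @param range one of `"Full"`, `"R1"`, `"R2"`, `"R3"` (see
#'   [spectralRanges()]) or a numeric `c(high, low)` pair in cm-1
#' @return a `SpectrumSet` restricted to the range
#' @export
setGeneric("extractRange", function(s, range) standardGeneric("extractRange"))

#' Variable importance in projection
#'
#' @param m a fitted model
#' @param ... passed to methods
#' @return numeric VIP vector (one entry per predictor), or for SO-PLS
#'   models a list with one VIP vector per block
#' @export
setGeneric("vipScores", function(m, ...) standardGeneric("vipScores"))
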