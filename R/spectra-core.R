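#' Construct a SpectrumSet
#'
#' @param wavenumbers numeric axis in cm-1, strictly monotone descending
#' @param values numeric matrix of intensities, one row per record, one
#'   column per wavenumber
#' @param meta data.frame with columns `record_id`, `subject_id`,
#'   `replicate`, `label` (1 = GDM, 0 = NGT), one row per record, matched to
#'   `values` rows by position
#' @param unit `"reflectance"` or `"absorbance"`
#' @return a validated [SpectrumSet-class] object
#' @examples
#' s <- SpectrumSet(c(5000, 4998, 4996),
#'                  matrix(runif(6, 0.2, 0.9), nrow = 2),
#'                  data.frame(record_id = c("a", "b"),
#'                             subject_id = c("S1", "S1"),
#'                             replicate = 1:2, label = c(0, 0)),
#'                  unit = "reflectance")
#' wavenumbers(s)
#' @export
SpectrumSet <- function(wavenumbers, values,
                        meta, unit = c("absorbance", "reflectance")) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    if (ncol(values) != length(wavenumbers))
        stop("value matrix has ", ncol(values),
             " columns but the axis has ", length(wavenumbers),
             " wavenumbers", call. = FALSE)
    if (nrow(values) != nrow(meta))
        stop("value matrix has ", nrow(values), " rows but the manifest has ",
             nrow(meta), " records", call. = FALSE)
    meta <- S4Vectors::DataFrame(
        record_id = as.character(meta$record_id),
        subject_id = as.character(meta$subject_id),
        replicate = as.integer(meta$replicate),
        label = as.integer(meta$label))
    assaym <- t(values)
    dimnames(assaym) <- list(NULL, meta$record_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = assaym),
        rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
        colData = meta,
        metadata = list(unit = unit))
    new("SpectrumSet", se)
}

#' @rdname SpectrumSet
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x)
    SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname SpectrumSet
#' @export
setMethod("intensityMat", "SpectrumSet", function(x) {
    m <- t(SummarizedExperiment::assay(x, "intensity"))
    colnames(m) <- as.character(wavenumbers(x))
    rownames(m) <- SummarizedExperiment::colData(x)$record_id
    m
})

#' @rdname SpectrumSet
#' @export
setMethod("unitType", "SpectrumSet", function(x)
    S4Vectors::metadata(x)$unit)

#' @rdname SpectrumSet
#' @export
setMethod("subjectIds", "SpectrumSet", function(x)
    SummarizedExperiment::colData(x)$subject_id)

#' @rdname SpectrumSet
#' @export
setMethod("classLabels", "SpectrumSet", function(x)
    SummarizedExperiment::colData(x)$label)

setMethod("show", "SpectrumSet", function(object) {
    wn <- wavenumbers(object)
    cat("SpectrumSet:", ncol(object), "records x", nrow(object),
        "spectral variables\n")
    cat("  axis:", format(max(wn), big.mark = ","), "->",
        format(min(wn), big.mark = ","), "cm-1 |  unit:",
        unitType(object), "\n")
    lab <- classLabels(object)
    cat("  subjects:", length(unique(subjectIds(object))),
        " (GDM records:", sum(lab == 1L), "/ NGT records:",
        sum(lab == 0L), ")\n")
})

#' The four canonical wavenumber ranges
#'
#' Full span 10,500-4000 cm-1 and its three sub-ranges: R1 10,500-7600
#' (high noise), R2 7600-5100 (varying noise), R3 5100-4000 (low noise).
#' Bounds are closed; touching bounds belong to both neighbours.
#'
#' @return named list of `c(high, low)` pairs in cm-1
#' @export
spectralRanges <- function() {
    list(Full = c(10500, 4000), R1 = c(10500, 7600),
         R2 = c(7600, 5100), R3 = c(5100, 4000))
}

.rangeBounds <- function(range) {
    if (is.numeric(range)) {
        stopifnot(length(range) == 2L)
        return(sort(range, decreasing = TRUE))
    }
    rr <- spectralRanges()
    if (!range %in% names(rr))
        stop("unknown range '", range, "'; expected one of ",
             paste(names(rr), collapse = ", "), call. = FALSE)
    rr[[range]]
}

#' @rdname extractRange
#' @export
setMethod("extractRange", "SpectrumSet", function(s, range) {
    b <- .rangeBounds(range)
    wn <- wavenumbers(s)
    tol <- if (length(wn) > 1L) stats::median(abs(diff(wn))) else 0
    if (max(wn) < b[1] - tol || min(wn) > b[2] + tol)
        stop("requested range [", b[2], ", ", b[1],
             "] cm-1 lies outside the axis span [", min(wn), ", ",
             max(wn), "]", call. = FALSE)
    keep <- wn <= b[1] & wn >= b[2]
    s[keep, ]
})

#' @rdname reflectanceToAbsorbance
#' @export
setMethod("reflectanceToAbsorbance", "SpectrumSet", function(s) {
    if (unitType(s) != "reflectance")
        stop("spectra are already in absorbance units", call. = FALSE)
    v <- SummarizedExperiment::assay(s, "intensity")
    if (any(v <= 0)) {
        bad <- unique(colnames(v)[which(v <= 0, arr.ind = TRUE)[, 2L]])
        stop("non-positive reflectance in record(s): ",
             paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    SummarizedExperiment::assay(s, "intensity") <- log10(1 / v)
    S4Vectors::metadata(s)$unit <- "absorbance"
    validObject(s)
    s
})

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectrumSet", function(s, expected = 5L) {
    cd <- SummarizedExperiment::colData(s)
    subj <- unique(cd$subject_id)
    v <- SummarizedExperiment::assay(s, "intensity")
    out <- matrix(0, nrow = nrow(v), ncol = length(subj))
    nrep <- integer(length(subj))
    lab <- integer(length(subj))
    for (i in seq_along(subj)) {
        idx <- which(cd$subject_id == subj[i])
        nrep[i] <- length(idx)
        lab[i] <- cd$label[idx[1L]]
        out[, i] <- rowMeans(v[, idx, drop = FALSE])
    }
    if (any(nrep != expected))
        warning(sum(nrep != expected), " subject(s) have a replicate count",
                " different from ", expected, call. = FALSE)
    colnames(out) <- subj
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = out),
        rowData = SummarizedExperiment::rowData(s),
        colData = S4Vectors::DataFrame(
            record_id = subj, subject_id = subj,
            replicate = rep(1L, length(subj)), label = lab,
            n_replicates = nrep),
        metadata = S4Vectors::metadata(s))
    new("SpectrumSet", se)
})

.delim <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read spectra and their manifest from delimited text
#'
#' The spectra file is a wide matrix: first column `record_id`, remaining
#' column names the wavenumbers in cm-1. The manifest maps each record to
#' its subject, replicate index and class label, with columns `record_id`,
#' `subject_id`, `replicate`, `label`. Field separator is autodetected from
#' the extension (`.csv` comma, otherwise tab).
#'
#' @param path path to the spectra file
#' @param manifest path to the manifest file
#' @param unit intensity unit of the stored values
#' @return a [SpectrumSet-class]
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, manifest,
                        unit = c("absorbance", "reflectance")) {
    unit <- match.arg(unit)
    sp <- read.csv(path, sep = .delim(path), check.names = FALSE)
    if (colnames(sp)[1L] != "record_id")
        stop("first column of the spectra file must be 'record_id'",
             call. = FALSE)
    wn <- suppressWarnings(as.numeric(colnames(sp)[-1L]))
    if (anyNA(wn))
        stop("non-numeric wavenumber header at column(s): ",
             paste(which(is.na(wn)) + 1L, collapse = ", "), call. = FALSE)
    vals <- as.matrix(sp[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
        bad <- which(!vapply(sp[-1L], is.numeric, logical(1L)))
        stop("non-numeric intensity values in column(s): ",
             paste(colnames(sp)[-1L][bad], collapse = ", "), call. = FALSE)
    }
    mf <- read.csv(manifest, sep = .delim(manifest))
    need <- c("record_id", "subject_id", "replicate", "label")
    if (!all(need %in% colnames(mf)))
        stop("manifest must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
    missing <- setdiff(mf$record_id, sp$record_id)
    if (length(missing))
        stop("manifest references absent record(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    extra <- setdiff(sp$record_id, mf$record_id)
    if (length(extra))
        stop("spectra records missing from manifest: ",
             paste(extra, collapse = ", "), call. = FALSE)
    mf <- mf[match(sp$record_id, mf$record_id), ]
    SpectrumSet(wn, vals, mf, unit = unit)
}

#' Write spectra and manifest as delimited text
#'
#' @param s a `SpectrumSet`
#' @param path output spectra file (`.csv` for comma, else tab)
#' @param manifest output manifest file
#' @return invisibly, the input `s`
#' @export
writeSpectra <- function(s, path, manifest) {
    m <- intensityMat(s)
    df <- data.frame(record_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = .delim(path), row.names = FALSE,
                quote = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(s))
    write.table(cd[, c("record_id", "subject_id", "replicate", "label")],
                manifest, sep = .delim(manifest), row.names = FALSE,
                quote = FALSE)
    invisible(s)
}
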