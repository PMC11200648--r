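#' Screen pretreatment combinations across spectral ranges
#'
#' Runs one full repeated double cross-validation per (range x
#' pretreatment) cell on subject-level absorbance spectra. Row-wise
#' pretreatment operators (smoothing/derivative, SNV, WLS baseline,
#' 2-norm) act on each spectrum independently and are applied once,
#' outside the CV loops -- they carry no cross-sample state, so this leaks
#' nothing; the column scaler (mean centering, or autoscaling if the spec
#' ends in `AS`) and the latent-variable count are learned strictly inside
#' each outer-training partition by the DCV engine. Every cell uses the
#' same master seed, so cells are directly comparable and the whole table
#' is deterministic.
#'
#' @param spectra a subject-level absorbance [SpectrumSet-class] (average
#'   replicates and convert units first)
#' @param grid named list of pretreatment specs, see
#'   [buildPretreatmentGrid()]
#' @param ranges character subset of `c("Full", "R1", "R2", "R3")`
#' @param cfg a [dcvConfig()]
#' @return object of class `"gdmScreening"`: a list with `table` (one row
#'   per cell: range, pretreatment, Sp/Se/NER/AUROC mean and SD, `ok`
#'   flag), `results` (the [DCVResult-class] per cell), `wavenumbers`
#'   (per-range axis) and `configHash`
#' @seealso [bestPerRange()], [reportBest()]
#' @export
runScreening <- function(spectra, grid = buildPretreatmentGrid(),
                         ranges = c("Full", "R1", "R2", "R3"),
                         cfg = dcvConfig()) {
    if (!length(ranges)) stop("at least one range required", call. = FALSE)
    if (unitType(spectra) != "absorbance")
        stop("spectra must be in absorbance units", call. = FALSE)
    y <- classLabels(spectra)
    rows <- list(); results <- list(); axes <- list()
    for (rg in ranges) {
        sub <- extractRange(spectra, rg)
        X <- intensityMat(sub)
        axes[[rg]] <- wavenumbers(sub)
        for (nm in names(grid)) {
            spec <- grid[[nm]]
            key <- paste(rg, nm, sep = " | ")
            cell <- tryCatch({
                prep <- .splitScaler(spec)
                Xrow <- if (length(prep$rowSteps$steps))
                    applyPretreatment(X, prep$rowSteps)$X else X
                builder <- plsLdaBuilder(aMax = cfg$aMax,
                    priors = cfg$priors,
                    autoscale = identical(prep$scaler, "autoscale"))
                dcvRun(Xrow, y, builder, cfg)
            }, error = function(e) e)
            if (inherits(cell, "error")) {
                warning("cell ", key, " failed: ",
                        conditionMessage(cell), call. = FALSE)
                rows[[key]] <- data.frame(range = rg, pretreatment = nm,
                    Sp_mean = NA, Sp_sd = NA, Se_mean = NA, Se_sd = NA,
                    NER_mean = NA, NER_sd = NA, AUROC_mean = NA,
                    AUROC_sd = NA, ok = FALSE)
            } else {
                rows[[key]] <- cbind(data.frame(range = rg,
                    pretreatment = nm), dcvSummary(cell), ok = TRUE)
                results[[key]] <- cell
            }
        }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    structure(list(table = tab, results = results, wavenumbers = axes,
                   config = cfg, configHash = .configHash(list(cfg,
                       names(grid), ranges))),
              class = "gdmScreening")
}

.splitScaler <- function(spec) {
    ops <- vapply(spec$steps, function(s) s$op, character(1L))
    isSc <- ops %in% c("mean_center", "autoscale")
    list(rowSteps = structure(list(steps = spec$steps[!isSc]),
                              class = "PretreatmentSpec"),
         scaler = if (any(isSc)) ops[isSc] else "mean_center")
}

.configHash <- function(x) {
    raw <- serialize(x, NULL, version = 2L)[-seq_len(14L)]
    sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %%
            .Machine$integer.max)
}

#' @export
print.gdmScreening <- function(x, ...) {
    cat("<gdmScreening>", nrow(x$table), "cells; best per range:\n")
    print(bestPerRange(x), row.names = FALSE)
    invisible(x)
}

#' Best pretreatment per spectral range
#'
#' Rows are ranked by mean NER; exact NER ties (possible when a range
#' classifies every subject correctly in every repetition) are broken by
#' mean AUROC, which remains informative after the 0/1 label metrics
#' saturate.
#'
#' @param screening a `"gdmScreening"` from [runScreening()]
#' @return the screening table restricted to the best row of each range,
#'   sorted best first
#' @export
bestPerRange <- function(screening) {
    tab <- screening$table[screening$table$ok, ]
    best <- do.call(rbind, lapply(split(tab, tab$range), function(d)
        d[order(-d$NER_mean, -d$AUROC_mean)[1L], ]))
    best <- best[order(-best$NER_mean, -best$AUROC_mean), ]
    rownames(best) <- NULL
    best
}

#' Report the best screened model: ROC curves, VIP intervals, metadata
#'
#' Collects, for the best cell (highest mean NER, optionally restricted to
#' one range), the repetition-level and vertically averaged ROC curves,
#' the VIP vector averaged over every outer-fold model of every
#' repetition, the relevant variables (average VIP > 1) merged into
#' contiguous wavenumber intervals, and run metadata (seed, configuration
#' hash). With `outDir` set, everything is also written as delimited text.
#'
#' @param screening a `"gdmScreening"` from [runScreening()]
#' @param range restrict the choice to one range (default: best overall)
#' @param vipGap interval merging gap in points, see [mergeVipIntervals()]
#' @param outDir optional output directory
#' @return list with `best` (table row), `roc` ([averageRoc()] output),
#'   `aurocMean`, `aurocSd`, `avgVip`, `intervals`, `meta`
#' @export
reportBest <- function(screening, range = NULL, vipGap = 3L,
                       outDir = NULL) {
    tab <- screening$table[screening$table$ok, ]
    if (!is.null(range)) tab <- tab[tab$range == range, ]
    if (!nrow(tab)) stop("no completed screening rows", call. = FALSE)
    bestRow <- tab[which.max(tab$NER_mean), ]
    key <- paste(bestRow$range, bestRow$pretreatment, sep = " | ")
    res <- screening$results[[key]]
    repSets <- lapply(res@scores, function(s)
        list(scores = s, labels = res@truth))
    roc <- averageRoc(repSets)
    avgVip <- dcvAverageVip(res)
    wn <- screening$wavenumbers[[bestRow$range]]
    intervals <- mergeVipIntervals(selectRelevant(avgVip), wn,
                                   gap = vipGap)
    meta <- data.frame(seed = res@config$seed,
                       repetitions = res@config$repetitions,
                       range = bestRow$range,
                       pretreatment = bestRow$pretreatment,
                       config_hash = screening$configHash)
    out <- list(best = bestRow, roc = roc,
                aurocMean = mean(res@metrics$AUROC),
                aurocSd = sd(res@metrics$AUROC),
                avgVip = avgVip, intervals = intervals, meta = meta)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeMetricsTable(cbind(bestRow, config_hash =
            screening$configHash), file.path(outDir, "best_model.csv"))
        write.table(roc$average, file.path(outDir, "roc_average.csv"),
                    sep = ",", row.names = FALSE, quote = FALSE)
        write.table(data.frame(fpr = roc$average$fpr, roc$curves),
                    file.path(outDir, "roc_curves.csv"), sep = ",",
                    row.names = FALSE, quote = FALSE)
        write.table(data.frame(wavenumber = wn, avg_vip = avgVip),
                    file.path(outDir, "vip.csv"), sep = ",",
                    row.names = FALSE, quote = FALSE)
        writeVipReport(intervals, avgVip, wn,
                       file.path(outDir, "vip_intervals.csv"))
        writeMetricsTable(meta, file.path(outDir, "run_meta.csv"))
    }
    out
}
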