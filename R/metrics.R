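#' Specificity, sensitivity and non-error rate from confusion counts
#'
#' With GDM as the positive class: `Sp = TN/(TN+FP)` (correct NGT calls),
#' `Se = TP/(TP+FN)` (correct GDM calls), and the non-error rate
#' `NER = (Sp + Se)/2` -- the balanced accuracy, which weights the two
#' classes equally regardless of cohort imbalance.
#'
#' @param tn,fp,fn,tp non-negative confusion counts
#' @return named numeric vector `c(Sp, Se, NER)`
#' @examples
#' spSeNer(tn = 66, fp = 1, fn = 10, tp = 5)  # NER 0.6592
#' @export
spSeNer <- function(tn, fp, fn, tp) {
    counts <- c(tn, fp, fn, tp)
    if (any(counts < 0)) stop("negative confusion count", call. = FALSE)
    if (tn + fp == 0 || fn + tp == 0)
        stop("a class is empty; Sp/Se undefined", call. = FALSE)
    sp <- tn / (tn + fp)
    se <- tp / (tp + fn)
    c(Sp = sp, Se = se, NER = (sp + se) / 2)
}

#' Confusion counts of a single binary-variable rule
#'
#' Evaluates the deterministic rule "predict GDM iff the variable is
#' positive" from the printed per-class positive counts of a covariate
#' table: `TP = pos_in_cases`, `FN = n_cases - TP`, `FP = pos_in_controls`,
#' `TN = n_controls - FP`.
#'
#' @param pos_in_cases,n_cases positives among, and total, GDM cases
#' @param pos_in_controls,n_controls positives among, and total, NGT
#'   controls
#' @return named integer vector `c(tn, fp, fn, tp)`
#' @examples
#' # prior-GDM history, second trimester cohort: Sp 1.0, Se 0.375
#' spSeNer(tn = 39, fp = 0, fn = 5, tp = 3)
#' do.call(spSeNer, as.list(binaryRuleEval(3, 8, 0, 39)))
#' @export
binaryRuleEval <- function(pos_in_cases, n_cases, pos_in_controls,
                           n_controls) {
    tp <- pos_in_cases; fn <- n_cases - tp
    fp <- pos_in_controls; tn <- n_controls - fp
    if (fn < 0 || tn < 0)
        stop("positive counts exceed class sizes", call. = FALSE)
    c(tn = as.integer(tn), fp = as.integer(fp), fn = as.integer(fn),
      tp = as.integer(tp))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted
#' one-half -- identical to the trapezoidal area under the empirical ROC
#' curve. Higher scores must mean "more GDM-like".
#'
#' @param scores numeric scores
#' @param labels binary labels (1 = GDM)
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("AUROC undefined with a single class", call. = FALSE)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohort prevalence of the positive class
#'
#' @param labels binary labels (1 = GDM)
#' @param digits decimals of the reported percentage (default 1)
#' @return percentage of positives, `100 * positives / total`
#' @examples
#' prevalence(rep(c(1, 0), c(15, 67)))  # 18.3
#' @export
prevalence <- function(labels, digits = 1L) {
    if (!length(labels)) stop("empty label vector", call. = FALSE)
    round(100 * sum(labels == 1L) / length(labels), digits)
}

#' Empirical ROC curve of one score set
#'
#' @param scores,labels as in [auroc()]
#' @return data.frame with columns `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.integer(labels)
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]; sc <- scores[ord]
    tp <- cumsum(lab == 1L); fp <- cumsum(lab == 0L)
    ## collapse tied scores to a single operating point
    last <- c(sc[-1L] != sc[-length(sc)], TRUE)
    tpr <- c(0, tp[last] / sum(labels == 1L))
    fpr <- c(0, fp[last] / sum(labels == 0L))
    data.frame(fpr = fpr, tpr = tpr)
}

#' Vertically average ROC curves over repetitions
#'
#' Interpolates each repetition's empirical ROC onto a fixed
#' false-positive-rate grid (step-function interpolation, carrying the
#' highest TPR reached at or below each grid FPR) and reports the vertical
#' mean. Endpoints (0,0) and (1,1) are pinned.
#'
#' @param reps list of `list(scores = ..., labels = ...)` per repetition
#' @param fprGrid false-positive-rate grid (default 101 points on `[0,1]`)
#' @return list with `average` (data.frame `fpr`, `tpr`) and `curves`
#'   (matrix, one column per repetition on the grid)
#' @export
averageRoc <- function(reps, fprGrid = seq(0, 1, length.out = 101L)) {
    if (!length(reps)) stop("at least one repetition needed", call. = FALSE)
    curves <- vapply(reps, function(r) {
        rc <- rocCurve(r$scores, r$labels)
        ## step interpolation: max tpr with fpr <= grid point
        approx(rc$fpr, rc$tpr, xout = fprGrid, method = "constant",
               f = 0, ties = max, rule = 2)$y
    }, numeric(length(fprGrid)))
    curves <- matrix(curves, nrow = length(fprGrid))
    avg <- rowMeans(curves)
    avg[1L] <- 0; avg[length(avg)] <- 1
    list(average = data.frame(fpr = fprGrid, tpr = avg), curves = curves)
}

#' Write a screening metrics table as delimited text
#'
#' Produces the tabular shape used to report best models per spectral
#' range: range, pretreatment notation, Sp mean/SD, Se mean/SD, NER
#' mean/SD (and AUROC mean/SD when present).
#'
#' @param tab data.frame as returned by [runScreening()]
#' @param path output path (`.csv` comma, else tab)
#' @return invisibly, `tab`
#' @export
writeMetricsTable <- function(tab, path) {
    write.table(tab, path, sep = .delim(path), row.names = FALSE,
                quote = FALSE)
    invisible(tab)
}
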