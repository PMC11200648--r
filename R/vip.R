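#' @describeIn vipScores standard single-response PLS VIP:
#'   `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with
#'   `SS_a = q_a^2 t_a' t_a`, the response variance explained by component
#'   a. The mean of the squared VIP scores over the `p` variables is 1 by
#'   construction, which motivates the conventional "VIP > 1 is relevant"
#'   rule.
#' @export
setMethod("vipScores", "PLSModel", function(m, ...) {
    if (m@ncomp == 0L)
        stop("model has no components; fit it first", call. = FALSE)
    p <- nrow(m@weights)
    ss <- m@yLoadings^2 * colSums(m@scores^2)
    wn2 <- sweep(m@weights^2, 2L, colSums(m@weights^2), "/")
    drop(sqrt(p * (wn2 %*% ss) / sum(ss)))
})

#' @describeIn vipScores per-block VIP of a two-block SO-PLS model: each
#'   block's scores come from that block's PLS sub-model (block 2 fitted on
#'   the residual response). A zero-component second block yields `NULL`
#'   for that entry.
#' @export
setMethod("vipScores", "SOPLSModel", function(m, ...) {
    list(block1 = vipScores(m@block1),
         block2 = if (!is.null(m@block2) && m@block2@ncomp > 0L)
             vipScores(m@block2) else NULL)
})

#' Relevance mask from averaged VIP scores
#'
#' Strictly-greater comparison: variables with average VIP above the
#' threshold (1 by convention) are flagged relevant.
#'
#' @param avg_vip numeric vector of VIP scores averaged over models
#' @param threshold relevance cutoff (default 1)
#' @return logical mask
#' @export
selectRelevant <- function(avg_vip, threshold = 1) {
    avg_vip > threshold
}

#' Merge a relevance mask into contiguous spectral intervals
#'
#' Reports maximal runs of selected variables as wavenumber intervals,
#' merging runs separated by at most `gap` unselected points (intervals
#' "mainly composed" of relevant variables). The axis is descending, so
#' intervals are reported as (high, low) cm-1 pairs, sorted.
#'
#' @param mask logical relevance mask
#' @param wavenumbers numeric axis, same length, strictly descending
#' @param gap maximum number of unselected points bridged (default 3)
#' @return data.frame with columns `high`, `low`, `n_points` (selected and
#'   bridged points per interval); zero rows for an empty mask
#' @export
mergeVipIntervals <- function(mask, wavenumbers, gap = 3L) {
    stopifnot(length(mask) == length(wavenumbers))
    empty <- data.frame(high = numeric(0), low = numeric(0),
                        n_points = integer(0))
    idx <- which(mask)
    if (!length(idx)) return(empty)
    brk <- which(diff(idx) > gap + 1L)
    starts <- idx[c(1L, brk + 1L)]
    ends <- idx[c(brk, length(idx))]
    data.frame(high = wavenumbers[starts], low = wavenumbers[ends],
               n_points = ends - starts + 1L)
}

#' Write a VIP interval report as delimited text
#'
#' @param intervals data.frame from [mergeVipIntervals()]
#' @param avg_vip averaged VIP vector (for per-interval mean VIP)
#' @param wavenumbers spectral axis
#' @param path output path
#' @return invisibly, the report data.frame
#' @export
writeVipReport <- function(intervals, avg_vip, wavenumbers, path) {
    rep_ <- intervals
    rep_$mean_VIP <- vapply(seq_len(nrow(intervals)), function(i) {
        inb <- wavenumbers <= intervals$high[i] &
               wavenumbers >= intervals$low[i]
        mean(avg_vip[inb])
    }, numeric(1L))
    names(rep_) <- c("interval_high_cm-1", "interval_low_cm-1",
                     "n_points", "mean_VIP")
    write.table(rep_, path, sep = .delim(path), row.names = FALSE,
                quote = FALSE)
    invisible(rep_)
}
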