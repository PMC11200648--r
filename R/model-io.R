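#' Export a fitted PLS-LDA model as structured text
#'
#' Writes every reproducibility-relevant quantity — centering parameters,
#' weights, rotation, loadings, y-loadings, coefficients and the LDA
#' threshold — to a single tab-separated file with one `section  index
#' component  value` row per number. [importPLSLDA()] inverts it exactly
#' (up to decimal formatting, 17 significant digits).
#'
#' @param fit result of [plsLdaFit()]
#' @param path output path
#' @return invisibly, `path`
#' @export
exportPLSLDA <- function(fit, path) {
    m <- fit$pls; t <- fit$lda
    rows <- list(
        data.frame(section = "ncomp", index = 1L, component = 0L,
                   value = m@ncomp),
        data.frame(section = "xMeans", index = seq_along(m@xMeans),
                   component = 0L, value = m@xMeans),
        data.frame(section = "yMean", index = 1L, component = 0L,
                   value = m@yMean),
        data.frame(section = "coef", index = seq_along(m@coef),
                   component = 0L, value = m@coef),
        data.frame(section = "yLoadings", index = 1L,
                   component = seq_along(m@yLoadings),
                   value = m@yLoadings),
        data.frame(section = "threshold", index = 1L, component = 0L,
                   value = t@threshold),
        data.frame(section = "orientation", index = 1L, component = 0L,
                   value = as.numeric(t@orientation == "gdm_above")),
        data.frame(section = "priors", index = 1:2, component = 0L,
                   value = unname(t@priors)))
    for (nm in c("weights", "rotation", "xLoadings")) {
        mat <- slot(m, nm)
        if (length(mat))
            rows[[nm]] <- data.frame(section = nm,
                index = rep(seq_len(nrow(mat)), ncol(mat)),
                component = rep(seq_len(ncol(mat)), each = nrow(mat)),
                value = as.vector(mat))
    }
    tab <- do.call(rbind, rows)
    tab$value <- formatC(tab$value, digits = 17, format = "g")
    write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @describeIn exportPLSLDA read a model written by `exportPLSLDA()`;
#'   returns a list with elements `pls` and `lda` usable by
#'   [plsLdaClassify()]
#' @export
importPLSLDA <- function(path) {
    tab <- read.csv(path, sep = "\t")
    pick <- function(s) tab[tab$section == s, ]
    vec <- function(s) {
        d <- pick(s)
        d$value[order(d$index)]
    }
    mat <- function(s, p, a) {
        d <- pick(s)
        out <- matrix(0, p, a)
        out[cbind(d$index, d$component)] <- d$value
        out
    }
    a <- as.integer(pick("ncomp")$value)
    xm <- vec("xMeans")
    p <- length(xm)
    q <- pick("yLoadings")
    q <- q$value[order(q$component)]
    coef <- vec("coef")
    R <- mat("rotation", p, a)
    coefPath <- vapply(seq_len(max(a, 1L)), function(k)
        if (a) drop(R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)])
        else numeric(p), numeric(p))
    pls <- new("PLSModel", weights = mat("weights", p, a),
               rotation = R, scores = matrix(0, 0L, a),
               xLoadings = mat("xLoadings", p, a), yLoadings = q,
               coef = coef, coefPath = matrix(coefPath, nrow = p),
               xMeans = xm, yMean = pick("yMean")$value, ncomp = a)
    pri <- vec("priors")
    lda <- new("LDAThreshold", threshold = pick("threshold")$value,
               orientation = if (pick("orientation")$value == 1)
                   "gdm_above" else "gdm_below",
               means = c(m0 = NA_real_, m1 = NA_real_),
               pooledVar = NA_real_,
               priors = c(pi0 = pri[1L], pi1 = pri[2L]))
    list(pls = pls, lda = lda)
}
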