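#' Orthogonalize a predictor block against a score matrix
#'
#' Removes from `X2` the subspace spanned by the block-1 scores:
#' `X2_orth = X2 - T1 (T1'T1)^-1 T1' X2`, so that `T1' X2_orth = 0`.
#' A rank-deficient score matrix is handled with the pseudo-inverse
#' (with a warning).
#'
#' @param X2 centered second-block matrix
#' @param T1 block-1 score matrix, same row count
#' @return the orthogonalized matrix
#' @export
orthogonalizeBlock <- function(X2, T1) {
    X2 <- .asMatrix(X2); T1 <- .asMatrix(T1)
    if (nrow(X2) != nrow(T1))
        stop("row counts differ between X2 and T1", call. = FALSE)
    if (ncol(T1) == 0L) return(X2)
    G <- .projCoef(T1, X2)
    X2 - T1 %*% G
}

## (T1'T1)^-1 T1' X2, via pseudo-inverse when T1 is rank deficient
.projCoef <- function(T1, X2) {
    gram <- crossprod(T1)
    ok <- qr(gram)$rank == ncol(gram)
    if (ok) {
        solve(gram, crossprod(T1, X2))
    } else {
        warning("rank-deficient score matrix; using pseudo-inverse",
                call. = FALSE)
        sv <- svd(gram)
        pos <- sv$d > max(sv$d) * 1e-10
        ginv <- sv$v[, pos, drop = FALSE] %*%
            (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
        ginv %*% crossprod(T1, X2)
    }
}

#' Fit a two-block SO-PLS-LDA model
#'
#' Sequential orthogonalized PLS on two predictor blocks: (1) fit a PLS1
#' model of the binary response on block 1 with `A1` components; (2)
#' orthogonalize the (centered) second block against the block-1 scores;
#' (3) fit a PLS1 model of the step-1 residuals `e1 = y - yhat1` on the
#' orthogonalized block with `A2` components. The combined prediction is
#' `yhat_SO = yhat1 + yhat2`, and the class boundary is set by LDA on the
#' training `yhat_SO`. With `A2 = 0` the model reduces exactly to the
#' single-block PLS-LDA on block 1.
#'
#' @param X1 first predictor block (rows = samples)
#' @param X2 second predictor block
#' @param y binary labels (1 = GDM)
#' @param A1 components for block 1 (>= 1)
#' @param A2 components for the orthogonalized block 2 (>= 0)
#' @param priors LDA priors mode, see [ldaThreshold()]
#' @param quiet passed to [plsFit()]
#' @param blockOrder optional character names recording the order used
#' @return list with elements `model` ([SOPLSModel-class]) and `lda`
#'   ([LDAThreshold-class])
#' @export
soplsFit <- function(X1, X2, y, A1, A2, priors = "equal", quiet = FALSE,
                     blockOrder = c("block1", "block2")) {
    X1 <- .asMatrix(X1); X2 <- .asMatrix(X2)
    stopifnot(nrow(X1) == nrow(X2), nrow(X1) == length(y), A1 >= 1L,
              A2 >= 0L)
    m1 <- plsFit(X1, y, A1, quiet = quiet)
    yhat1 <- plsPredict(m1, X1)
    e1 <- y - yhat1
    x2m <- colMeans(X2)
    X2c <- sweep(X2, 2L, x2m, "-")
    if (m1@ncomp > 0L) {
        G <- .projCoef(m1@scores, X2c)
        X2o <- X2c - m1@scores %*% G
    } else {
        G <- matrix(0, 0L, ncol(X2))
        X2o <- X2c
    }
    m2 <- if (A2 >= 1L) plsFit(X2o, e1, A2, quiet = quiet) else NULL
    yhat2 <- if (is.null(m2)) rep(0, nrow(X1)) else plsPredict(m2, X2o)
    fitted <- yhat1 + yhat2
    model <- new("SOPLSModel", block1 = m1, block2 = m2, x2Means = x2m,
                 orthCoef = G, fitted = fitted, blockOrder = blockOrder)
    list(model = model, lda = ldaThreshold(fitted, y, priors))
}

setMethod("show", "SOPLSModel", function(object) {
    a2 <- if (is.null(object@block2)) 0L else object@block2@ncomp
    cat("SOPLSModel: blocks", paste(object@blockOrder, collapse = " -> "),
        sprintf("(A1 = %d, A2 = %d)\n", object@block1@ncomp, a2))
})

#' Predict combined responses from an SO-PLS model
#'
#' New second-block rows are centered with the training means and
#' orthogonalized through the training projection, using block-1 scores
#' predicted for the new samples: `X2_orth = X2c - T1_new G`, with `G`
#' learned during fitting. Then
#' `yhat_SO = yhat1(X1_new) + yhat2(X2_orth)`.
#'
#' @param m an [SOPLSModel-class]
#' @param X1_new,X2_new new predictor blocks
#' @return numeric vector of combined predicted responses
#' @export
soplsPredict <- function(m, X1_new, X2_new) {
    X1_new <- .asMatrix(X1_new); X2_new <- .asMatrix(X2_new)
    yhat1 <- plsPredict(m@block1, X1_new)
    if (is.null(m@block2)) return(yhat1)
    X2c <- sweep(X2_new, 2L, m@x2Means, "-")
    if (m@block1@ncomp > 0L) {
        T1new <- plsScores(m@block1, X1_new)
        X2c <- X2c - T1new %*% m@orthCoef
    }
    yhat1 + plsPredict(m@block2, X2c)
}

#' @describeIn soplsPredict classify new samples with the fitted threshold
#' @param fit result of [soplsFit()]
#' @export
soplsClassify <- function(fit, X1_new, X2_new) {
    ldaClassify(fit$lda, soplsPredict(fit$model, X1_new, X2_new))
}
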