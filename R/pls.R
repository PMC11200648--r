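#' Fit a single-response PLS regression (PLS1) by NIPALS
#'
#' Extracts `A` components sequentially with X-deflation. The first weight
#' vector is proportional to `X'y`; each score has maximal covariance with
#' the (deflated) response. After centering, the model satisfies
#' `T = Xc R` and `b = R q`, where `R = W (P'W)^-1` maps the centered
#' training matrix to the scores. Predictions computed through the scores
#' (`yhat = T q`) and through the coefficients (`yhat = Xc b`) coincide.
#'
#' Components whose weight or score norm falls below numerical rank
#' tolerance stop the extraction; if fewer than `A` components can be
#' extracted a warning is raised (suppress with `quiet = TRUE`) and the
#' model keeps the extracted count.
#'
#' @param X numeric predictor matrix (rows = samples); centered internally
#' @param y numeric response; for classification the binary coding
#'   1 = GDM, 0 = NGT
#' @param A number of components (latent variables) requested
#' @param quiet suppress the rank-truncation warning
#' @return a [PLSModel-class]
#' @export
plsFit <- function(X, y, A, quiet = FALSE) {
    X <- .asMatrix(X)
    y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    stopifnot(length(y) == n)
    if (A < 1L) stop("A must be >= 1", call. = FALSE)
    if (A > min(n - 1L, p) && !quiet)
        warning("A reduced from ", A, " to ", min(n - 1L, p),
                " (sample/variable limit)", call. = FALSE)
    core <- .plsFitCore(X, y, A)
    if (core$a == 0L)
        ## response carries no covariance with X: null model
        return(new("PLSModel", weights = core$W, rotation = core$R,
                   scores = core$Tm, xLoadings = core$P,
                   yLoadings = core$q, coef = numeric(p),
                   coefPath = core$coefPath, xMeans = core$xm,
                   yMean = core$ym, ncomp = 0L))
    if (core$a < core$requested && !quiet)
        warning("A reduced from ", core$requested, " to ", core$a,
                " (rank limit)", call. = FALSE)
    new("PLSModel", weights = core$W, rotation = core$R,
        scores = core$Tm, xLoadings = core$P, yLoadings = core$q,
        coef = core$coefPath[, core$a], coefPath = core$coefPath,
        xMeans = core$xm, yMean = core$ym, ncomp = core$a)
}

setMethod("show", "PLSModel", function(object) {
    cat("PLSModel:", object@ncomp, "component(s),",
        length(object@coef), "variables\n")
})

#' Predict responses from a PLS model
#'
#' `yhat = (X_new - training means) b + training y-mean`. With
#' `ncomp` smaller than the fitted count, the coefficient path of the
#' nested sub-model with that many components is used.
#'
#' @param m a [PLSModel-class]
#' @param X_new matrix with the training variable count
#' @param ncomp number of components to use (default: all fitted)
#' @return numeric vector of predicted responses
#' @export
plsPredict <- function(m, X_new, ncomp = m@ncomp) {
    X_new <- .asMatrix(X_new)
    if (ncol(X_new) != length(m@xMeans))
        stop("X_new has ", ncol(X_new), " columns; model was trained on ",
             length(m@xMeans), call. = FALSE)
    if (m@ncomp == 0L) return(rep(m@yMean, nrow(X_new)))
    stopifnot(ncomp >= 1L, ncomp <= m@ncomp)
    Xc <- sweep(X_new, 2L, m@xMeans, "-")
    drop(Xc %*% m@coefPath[, ncomp]) + m@yMean
}

#' Predicted scores for new samples
#'
#' @param m a [PLSModel-class]
#' @param X_new matrix with the training variable count
#' @return score matrix `(X_new - means) R`
#' @export
plsScores <- function(m, X_new) {
    X_new <- .asMatrix(X_new)
    sweep(X_new, 2L, m@xMeans, "-") %*% m@rotation
}

#' Fitted training responses along the component path
#'
#' Column a holds the fitted values of the nested a-component model,
#' computed through the score route `yhat = T q`.
#'
#' @param m a [PLSModel-class]
#' @return matrix (training rows x ncomp)
#' @export
plsFittedPath <- function(m) {
    if (m@ncomp == 0L)
        return(matrix(m@yMean, nrow(m@scores), 1L))
    contrib <- sweep(m@scores, 2L, m@yLoadings, "*")
    path <- contrib
    if (m@ncomp > 1L)
        path <- t(apply(contrib, 1L, cumsum))
    path + m@yMean
}

#' One-dimensional LDA threshold on predicted responses
#'
#' Two-class linear discriminant analysis on the scalar predicted response:
#' with class means `m0`, `m1`, pooled within-class variance `s2` and
#' priors `pi0`, `pi1`, the decision threshold is
#' `(m0 + m1)/2 + s2 * log(pi0/pi1) / (m1 - m0)`. The orientation records
#' which side of the threshold is the GDM side (the side of `m1`).
#'
#' @param y_hat numeric predicted responses on the training set
#' @param y binary observed labels (1 = GDM)
#' @param priors `"equal"` (default) or `"proportional"` to class sizes
#' @return an [LDAThreshold-class]
#' @export
ldaThreshold <- function(y_hat, y, priors = c("equal", "proportional")) {
    priors <- match.arg(priors)
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
        stop("both classes must be present", call. = FALSE)
    i0 <- y == 0L; i1 <- y == 1L
    n0 <- sum(i0); n1 <- sum(i1)
    pi_ <- if (priors == "equal") c(0.5, 0.5) else c(n0, n1) / (n0 + n1)
    core <- .ldaCore(y_hat, i0, i1, n0, n1,
                     .priorLogRatio(priors, n0, n1))
    if (is.null(core))
        stop("degenerate separation: identical class means", call. = FALSE)
    new("LDAThreshold", threshold = core$thr,
        orientation = if (core$up) "gdm_above" else "gdm_below",
        means = c(m0 = core$m0, m1 = core$m1), pooledVar = core$s2,
        priors = c(pi0 = pi_[1L], pi1 = pi_[2L]))
}

setMethod("show", "LDAThreshold", function(object) {
    cat("LDAThreshold:", signif(object@threshold, 6),
        sprintf("(%s; priors %0.2f/%0.2f)\n", object@orientation,
                object@priors[1L], object@priors[2L]))
})

#' Classify predicted responses with an LDA threshold
#'
#' A sample is labelled GDM (1) when its predicted response lies strictly
#' on the GDM side of the threshold; exact ties go to NGT (0),
#' deterministically.
#'
#' @param t an [LDAThreshold-class]
#' @param y_hat numeric predicted responses
#' @return integer vector of 0/1 labels
#' @export
ldaClassify <- function(t, y_hat) {
    if (t@orientation == "gdm_above")
        as.integer(y_hat > t@threshold)
    else
        as.integer(y_hat < t@threshold)
}

#' Fit and classify with single-block PLS-LDA
#'
#' Convenience wrapper: PLS1 on the binary-coded response, then LDA on the
#' fitted responses to set the decision threshold.
#'
#' @param X predictor matrix
#' @param y binary labels (1 = GDM)
#' @param A number of latent variables
#' @param priors LDA priors mode, see [ldaThreshold()]
#' @param quiet passed to [plsFit()]
#' @return list with elements `pls` ([PLSModel-class]) and `lda`
#'   ([LDAThreshold-class])
#' @export
plsLdaFit <- function(X, y, A, priors = "equal", quiet = FALSE) {
    m <- plsFit(X, y, A, quiet = quiet)
    yhat <- plsPredict(m, X)
    list(pls = m, lda = ldaThreshold(yhat, y, priors))
}

#' @describeIn plsLdaFit predict 0/1 labels for new samples
#' @param fit result of `plsLdaFit()`
#' @param X_new new predictor matrix
#' @export
plsLdaClassify <- function(fit, X_new) {
    ldaClassify(fit$lda, plsPredict(fit$pls, X_new))
}
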