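## Internal PLS1/LDA computational cores.
## Plain-list versions of the fitting routines, shared by the exported S4
## API and by the cross-validation hot path (where S4 construction and
## validity checking would dominate the runtime of the many thousand fits
## a screening run performs). All exported behaviour is defined by these
## cores, so the two routes cannot diverge.

## Kernel PLS1 with covariance-vector deflation (Dayal & MacGregor):
## deflating s = Xd'y instead of X itself gives the NIPALS solution with
## two n x p products per component and no n x p temporaries. The weights
## W, scores T, loadings P and y-loadings q are identical to NIPALS with
## X deflation; R accumulates the rotation so that T = Xc R directly.
## The compiled kernel (src/pls_kernel.cpp) is the production path; this
## R implementation of the same recursion is kept as a readable reference
## and exercised against the compiled one in the tests.
.plsFitCore <- function(X, y, A) {
    out <- .plsKernelCpp(X, as.numeric(y), as.integer(A))
    out$xm <- as.numeric(out$xm)
    out
}

.plsFitCoreR <- function(X, y, A) {
    n <- nrow(X); p <- ncol(X)
    A <- min(A, n - 1L, p)
    xm <- colMeans(X); ym <- mean(y)
    yc <- y - ym
    ssx <- sum(X * X) - n * sum(xm * xm)
    tolr <- 1e-12 * max(1, ssx)
    W <- matrix(0, p, A); P <- matrix(0, p, A)
    R <- matrix(0, p, A); Tm <- matrix(0, n, A); q <- numeric(A)
    s <- crossprod(X, yc)            # = Xc'yc since sum(yc) = 0
    a <- 0L
    for (k in seq_len(A)) {
        wn2 <- sum(s^2)
        if (wn2 <= tolr * 1e-6 || wn2 == 0) break
        w <- s / sqrt(wn2)
        r <- w
        if (k > 1L) {
            jj <- seq_len(k - 1L)
            r <- r - R[, jj, drop = FALSE] %*%
                crossprod(P[, jj, drop = FALSE], w)
        }
        tt_ <- drop(X %*% r) - drop(crossprod(xm, r))
        tss <- sum(tt_^2)
        if (tss <= tolr) break
        pv <- (crossprod(X, tt_) - xm * sum(tt_)) / tss
        qk <- sum(yc * tt_) / tss
        s <- s - pv * (qk * tss)
        a <- k
        W[, k] <- w; P[, k] <- pv; R[, k] <- r
        Tm[, k] <- tt_; q[k] <- qk
    }
    if (a == 0L)
        return(list(W = matrix(0, p, 0), R = matrix(0, p, 0),
                    Tm = matrix(0, n, 0), P = matrix(0, p, 0),
                    q = numeric(0), coefPath = matrix(0, p, 1L),
                    xm = xm, ym = ym, a = 0L, requested = A))
    idx <- seq_len(a)
    W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
    R <- R[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
    q <- q[idx]
    coefPath <- matrix(0, p, a)
    acc <- numeric(p)
    for (k in idx) {
        acc <- acc + R[, k] * q[k]
        coefPath[, k] <- acc
    }
    list(W = W, R = R, Tm = Tm, P = P, q = q, coefPath = coefPath,
         xm = xm, ym = ym, a = a, requested = A)
}

.corePredict <- function(core, X, ncomp = core$a) {
    if (core$a == 0L) return(rep(core$ym, nrow(X)))
    b <- core$coefPath[, min(ncomp, core$a)]
    drop(X %*% b) + (core$ym - sum(core$xm * b))
}

## n x a matrix of fitted training responses along the component path
.coreFittedPath <- function(core) {
    if (core$a == 0L) return(matrix(core$ym, nrow(core$Tm), 1L))
    n <- nrow(core$Tm); a <- core$a
    contrib <- core$Tm * matrix(core$q, n, a, byrow = TRUE)
    ones <- upper.tri(diag(a), diag = TRUE) * 1
    contrib %*% ones + core$ym
}

.coreVip <- function(core) {
    p <- nrow(core$W)
    ss <- core$q^2 * colSums(core$Tm^2)
    wn2 <- sweep(core$W^2, 2L, colSums(core$W^2), "/")
    drop(sqrt(p * (wn2 %*% ss) / sum(ss)))
}

## one-dimensional two-class LDA threshold; returns NULL when degenerate
.ldaCore <- function(y_hat, i0, i1, n0, n1, priorLogRatio) {
    m0 <- mean(y_hat[i0]); m1 <- mean(y_hat[i1])
    if (m1 == m0) return(NULL)
    s2 <- (sum((y_hat[i0] - m0)^2) + sum((y_hat[i1] - m1)^2)) /
        max(n0 + n1 - 2L, 1L)
    list(thr = (m0 + m1) / 2 + s2 * priorLogRatio / (m1 - m0),
         up = m1 > m0, m0 = m0, m1 = m1, s2 = s2)
}

## vectorized over the columns of a fitted-response path matrix
.ldaPathCore <- function(path, y, priorLogRatio) {
    i0 <- y == 0L; i1 <- y == 1L
    n0 <- sum(i0); n1 <- sum(i1)
    p0 <- path[i0, , drop = FALSE]; p1 <- path[i1, , drop = FALSE]
    m0 <- colMeans(p0); m1 <- colMeans(p1)
    s2 <- (colSums(p0^2) - n0 * m0^2 + colSums(p1^2) - n1 * m1^2) /
        max(n0 + n1 - 2L, 1L)
    d <- m1 - m0
    thr <- (m0 + m1) / 2 + ifelse(d != 0, s2 * priorLogRatio / d, NA_real_)
    list(thr = thr, up = d > 0, valid = d != 0)
}

.priorLogRatio <- function(priors, n0, n1) {
    if (priors == "equal") 0 else log(n0 / n1)
}

.coreClassify <- function(up, thr, y_hat) {
    if (up) as.integer(y_hat > thr) else as.integer(y_hat < thr)
}
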