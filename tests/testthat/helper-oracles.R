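## Independent oracles, deliberately written with different algorithms
## than the package internals.

## SIMPLS (de Jong) for a single response; returns fitted training values.
## For one response block, SIMPLS and NIPALS-PLS1 span the same Krylov
## subspace, so fitted values must agree.
simplsFitted <- function(X, y, A) {
    n <- nrow(X)
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2L, xm, "-")
    yc <- y - ym
    S <- crossprod(Xc, yc)
    V <- NULL
    Tmat <- matrix(0, n, A)
    for (a in seq_len(A)) {
        r <- S
        t <- drop(Xc %*% r)
        t <- t / sqrt(sum(t^2))
        p <- crossprod(Xc, t)
        v <- p
        if (!is.null(V)) v <- v - V %*% crossprod(V, p)
        v <- v / sqrt(sum(v^2))
        S <- S - v %*% crossprod(v, S)
        V <- cbind(V, v)
        Tmat[, a] <- t
    }
    drop(Tmat %*% crossprod(Tmat, yc)) + ym
}

## AUROC by explicit pair counting
aurocBrute <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

## textbook VIP recomputation with explicit loops
vipBrute <- function(W, Tm, q) {
    p <- nrow(W); A <- ncol(W)
    ss <- numeric(A)
    for (a in seq_len(A)) ss[a] <- q[a]^2 * sum(Tm[, a]^2)
    out <- numeric(p)
    for (j in seq_len(p)) {
        num <- 0
        for (a in seq_len(A))
            num <- num + ss[a] * (W[j, a]^2 / sum(W[, a]^2))
        out[j] <- sqrt(p * num / sum(ss))
    }
    out
}

## Savitzky-Golay at interior point i: polynomial LSQ over the window,
## evaluated (or differentiated) at the window center
sgWindowOracle <- function(x, i, width, polyorder, deriv) {
    h <- (width - 1L) / 2L
    idx <- (i - h):(i + h)
    u <- idx - i
    fit <- lm(x[idx] ~ poly(u, polyorder, raw = TRUE))
    cf <- coef(fit)
    if (deriv == 0L) unname(cf[1L])
    else if (deriv == 1L) unname(cf[2L])
    else unname(2 * cf[3L])
}

## expected confusion of a hard rule from per-class counts
nerFromCounts <- function(posCases, nCases, posControls, nControls) {
    sp <- (nControls - posControls) / nControls
    se <- posCases / nCases
    (sp + se) / 2
}
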