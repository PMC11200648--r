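test_that("first PLS weight is the normalized covariance direction", {
    set.seed(21)
    X <- matrix(rnorm(60), 12)
    y <- rbinom(12, 1, 0.5)
    m <- plsFit(X, y, 2)
    w1 <- crossprod(scale(X, scale = FALSE), y - mean(y))
    w1 <- w1 / sqrt(sum(w1^2))
    expect_equal(drop(m@weights[, 1]), drop(w1), tolerance = 1e-10)
})

test_that("PLS at full rank equals least squares; scores stay orthogonal", {
    set.seed(22)
    for (rep in 1:5) {
        X <- matrix(rnorm(100), 20, 5)
        y <- rbinom(20, 1, 0.4)
        m <- plsFit(X, y, 5)
        expect_equal(plsPredict(m, X), unname(fitted(lm(y ~ X))),
                     tolerance = 1e-8)
        G <- crossprod(m@scores)
        expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
        ## model identities: T = Xc R and b = R q
        Xc <- sweep(X, 2, m@xMeans)
        expect_equal(Xc %*% m@rotation, m@scores, tolerance = 1e-8)
        expect_equal(drop(m@rotation %*% m@yLoadings), m@coef,
                     tolerance = 1e-10)
    }
})

test_that("compiled PLS kernel matches the R reference implementation", {
    set.seed(20)
    for (rep in 1:3) {
        X <- matrix(rnorm(45 * 30), 45)
        y <- rbinom(45, 1, 0.2)
        a <- gdmnir:::.plsFitCore(X, y, 5)
        b <- gdmnir:::.plsFitCoreR(X, y, 5)
        expect_equal(a$coefPath, b$coefPath, tolerance = 1e-12)
        expect_equal(a$Tm, b$Tm, tolerance = 1e-10)
        expect_equal(a$q, b$q, tolerance = 1e-12)
        expect_identical(a$a, b$a)
    }
})

test_that("PLS agrees with an independent SIMPLS implementation", {
    set.seed(23)
    for (A in 1:3) {
        X <- matrix(rnorm(15 * 8), 15)
        y <- rbinom(15, 1, 0.4)
        m <- plsFit(X, y, A)
        expect_equal(plsPredict(m, X), simplsFitted(X, y, A),
                     tolerance = 1e-8)
    }
})

test_that("score route and coefficient route give identical predictions", {
    set.seed(24)
    X <- matrix(rnorm(80), 16)
    y <- rbinom(16, 1, 0.5)
    m <- plsFit(X, y, 3)
    viaCoef <- plsPredict(m, X)
    viaScores <- drop(plsScores(m, X) %*% m@yLoadings) + m@yMean
    expect_equal(viaCoef, viaScores, tolerance = 1e-10)
    ## a new row equal to a training row reproduces its fitted value
    expect_equal(plsPredict(m, X[3, , drop = FALSE]), viaCoef[3],
                 tolerance = 1e-12)
    ## the fitted path ends at the full-model fitted values
    expect_equal(plsFittedPath(m)[, m@ncomp], viaCoef, tolerance = 1e-10)
    expect_error(plsPredict(m, X[, 1:3]), "columns")
})

test_that("residuals never increase with added components", {
    set.seed(25)
    X <- matrix(rnorm(30 * 10), 30)
    y <- rbinom(30, 1, 0.3)
    m <- plsFit(X, y, 6)
    rss <- colSums((y - plsFittedPath(m))^2)
    expect_true(all(diff(rss) <= 1e-10))
})

test_that("degenerate responses are handled: zero variance, rank limits", {
    set.seed(26)
    X <- matrix(rnorm(40), 8)
    m0 <- plsFit(X, rep(1, 8), 2, quiet = TRUE)
    expect_identical(m0@ncomp, 0L)
    expect_equal(m0@coef, rep(0, 5))
    expect_equal(plsPredict(m0, X), rep(1, 8))
    ## requesting more components than the rank allows warns and truncates
    X1 <- cbind(rnorm(8))
    expect_warning(m1 <- plsFit(X1, rbinom(8, 1, 0.5), 5), "reduced")
    expect_lte(m1@ncomp, 1L)
})

test_that("LDA threshold follows the pooled-variance closed form", {
    ## symmetric case: equal priors give the midpoint
    t1 <- ldaThreshold(c(0, 0.2, 0.8, 1), c(0, 0, 1, 1))
    expect_equal(t1@threshold, 0.5)
    expect_identical(t1@orientation, "gdm_above")
    ## equal priors give the midpoint whatever the variance
    set.seed(27)
    yh <- c(rnorm(10, 0, 2), rnorm(6, 3, 2))
    y <- rep(c(0L, 1L), c(10, 6))
    t2 <- ldaThreshold(yh, y, "equal")
    expect_equal(t2@threshold,
                 (mean(yh[y == 0]) + mean(yh[y == 1])) / 2,
                 tolerance = 1e-12)
    ## proportional priors match a brute-force posterior grid search
    t3 <- ldaThreshold(yh, y, "proportional")
    grid <- seq(min(yh), max(yh), length.out = 20001)
    p0 <- (10 / 16) * dnorm(grid, mean(yh[y == 0]), sqrt(t3@pooledVar))
    p1 <- (6 / 16) * dnorm(grid, mean(yh[y == 1]), sqrt(t3@pooledVar))
    cross <- grid[which(diff(sign(p1 - p0)) != 0)[1] + 1L]
    expect_equal(t3@threshold, cross, tolerance = 1e-2)
    expect_error(ldaThreshold(c(1, 1, 1, 1), c(0, 0, 1, 1)),
                 "degenerate")
    expect_error(ldaThreshold(c(1, 2), c(1, 1)), "both classes")
})

test_that("classification respects orientation and resolves ties to NGT", {
    t1 <- ldaThreshold(c(0, 0.2, 0.8, 1), c(0, 0, 1, 1))
    expect_identical(ldaClassify(t1, c(0.6, 0.4)), c(1L, 0L))
    ## exact ties go to class 0
    expect_identical(ldaClassify(t1, c(0.5, 0.5)), c(0L, 0L))
    ## flipped orientation: GDM below
    t2 <- ldaThreshold(c(1, 0.8, 0.2, 0), c(0, 0, 1, 1))
    expect_identical(t2@orientation, "gdm_below")
    expect_identical(ldaClassify(t2, c(0.6, 0.4)), c(0L, 1L))
})

test_that("models round-trip through the structured-text export", {
    d <- separableData(p = 4)
    fit <- plsLdaFit(d$X, d$y, 2)
    f <- withr::local_tempfile(fileext = ".tsv")
    exportPLSLDA(fit, f)
    back <- importPLSLDA(f)
    Xnew <- withr::with_seed(61, matrix(rnorm(5 * 4), 5))
    expect_equal(plsPredict(back$pls, Xnew), plsPredict(fit$pls, Xnew),
                 tolerance = 1e-12)
    expect_identical(plsLdaClassify(back, Xnew), plsLdaClassify(fit, Xnew))
    expect_equal(back$lda@threshold, fit$lda@threshold, tolerance = 1e-12)
})

test_that("PLS-LDA recovers separable training data and is affine invariant", {
    d <- separableData()
    fit <- plsLdaFit(d$X, d$y, 2)
    expect_identical(plsLdaClassify(fit, d$X), d$y)
    ## labels are invariant under increasing affine maps of scores+threshold
    yh <- plsPredict(fit$pls, d$X)
    lab <- ldaClassify(fit$lda, yh)
    t2 <- fit$lda
    t2@threshold <- 3 * t2@threshold + 1
    expect_identical(ldaClassify(t2, 3 * yh + 1), lab)
})
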