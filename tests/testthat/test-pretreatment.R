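test_that("Savitzky-Golay reproduces polynomials and slopes exactly", {
    p <- 41L
    i <- seq_len(p)
    quad <- 0.3 + 0.02 * i - 0.001 * i^2
    out <- savitzkyGolay(rbind(quad), width = 9L, polyorder = 2L,
                         deriv = 0L)
    expect_equal(drop(out), quad, tolerance = 1e-10)
    lin <- 2 * i
    d1 <- savitzkyGolay(rbind(lin), width = 5L, polyorder = 2L,
                        deriv = 1L)
    expect_equal(drop(d1), rep(2, p), tolerance = 1e-10)
    ## derivative of a constant row is zero
    d1c <- savitzkyGolay(rbind(rep(3, p)), width = 7L, deriv = 1L)
    expect_equal(drop(d1c), rep(0, p), tolerance = 1e-12)
    expect_error(savitzkyGolay(rbind(lin), width = 6L), "odd")
    expect_error(savitzkyGolay(rbind(lin), width = 43L), "exceeds")
})

test_that("Savitzky-Golay matches per-window least squares at interior points", {
    x <- withr::with_seed(8, rnorm(30))
    for (deriv in 0:2) {
        out <- drop(savitzkyGolay(rbind(x), width = 7L, polyorder = 2L,
                                  deriv = deriv))
        for (i in c(4L, 11L, 20L, 27L))
            expect_equal(out[i], sgWindowOracle(x, i, 7L, 2L, deriv),
                         tolerance = 1e-8)
    }
})

test_that("SNV centers and scales each spectrum independently", {
    expect_equal(drop(snv(rbind(c(1, 2, 3)))), c(-1, 0, 1))
    X <- withr::with_seed(3, matrix(rnorm(50), 5))
    out <- snv(X)
    expect_equal(unname(rowMeans(out)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(out, 1, sd)), rep(1, 5), tolerance = 1e-12)
    ## idempotent: snv of snv equals snv
    expect_equal(snv(out), out, tolerance = 1e-12)
    expect_error(snv(rbind(c(5, 5, 5))), "constant")
})

test_that("2-norm normalization yields unit rows and rejects zero rows", {
    expect_equal(drop(norm2(rbind(c(3, 4)))), c(0.6, 0.8))
    X <- withr::with_seed(4, matrix(rnorm(40), 4))
    out <- norm2(X)
    expect_equal(unname(sqrt(rowSums(out^2))), rep(1, 4),
                 tolerance = 1e-12)
    expect_equal(norm2(out), out, tolerance = 1e-12)
    expect_error(norm2(rbind(rep(0, 5))), "zero")
})

test_that("WLS baseline removes polynomial trends and preserves peaks", {
    p <- 101L
    u <- seq_len(p)
    line <- 0.5 + 0.01 * u
    expect_equal(drop(wlsBaseline(rbind(line), order = 1L)), rep(0, p),
                 tolerance = 1e-8)
    expect_equal(drop(wlsBaseline(rbind(rep(2, p)), order = 0L)),
                 rep(0, p), tolerance = 1e-8)
    ## line + positive Gaussian peak: correction approximates the peak;
    ## oracle = polynomial fitted to peak-free points only
    peak <- 2 * exp(-(u - 50)^2 / 18)
    x <- line + peak
    corrected <- drop(wlsBaseline(rbind(x), order = 1L))
    peakFree <- abs(u - 50) > 15
    oracleBase <- cbind(1, u) %*% coef(lm(x ~ u, subset = peakFree))
    expect_equal(corrected[50], (x - drop(oracleBase))[50],
                 tolerance = 0.05)
    expect_error(wlsBaseline(rbind(line), order = 200L), "order")
})

test_that("column scalers learn from training data only", {
    set.seed(9)
    Xtr <- matrix(rnorm(60), 10)
    Xte <- matrix(rnorm(30), 5)
    f <- fitColumnScaler(Xtr, "autoscale")
    out <- applyColumnScaler(f, Xtr)
    expect_equal(unname(colMeans(out)), rep(0, 6), tolerance = 1e-12)
    expect_equal(unname(apply(out, 2, sd)), rep(1, 6), tolerance = 1e-12)
    ## manual formula on test rows
    manual <- sweep(sweep(Xte, 2, colMeans(Xtr)), 2, apply(Xtr, 2, sd),
                    "/")
    expect_equal(applyColumnScaler(f, Xte), manual, tolerance = 1e-12)
    ## a test row equal to the training means maps to zero
    mc <- fitColumnScaler(Xtr, "mean_center")
    expect_equal(drop(applyColumnScaler(mc, rbind(colMeans(Xtr)))),
                 rep(0, 6), tolerance = 1e-12)
    ## no leakage: including test rows in the fit changes the output
    leaky <- fitColumnScaler(rbind(Xtr, Xte), "mean_center")
    expect_false(isTRUE(all.equal(applyColumnScaler(leaky, Xte),
                                  applyColumnScaler(mc, Xte))))
    ## constant columns under autoscale get scale 1 with a warning
    Xc <- Xtr; Xc[, 2] <- 7
    expect_warning(f2 <- fitColumnScaler(Xc, "autoscale"), "constant")
    expect_equal(f2$scale[2], 1)
    expect_error(applyColumnScaler(list(), Xte), "fitColumnScaler")
})

test_that("pretreatment DSL parses and prints round-trip", {
    for (txt in c("SM(W=23)+N+MC", "1D(W=15)+MC", "WLS+N+MC",
                  "2D(W=3)+N+MC", "SNV+MC", "N+AS", "raw")) {
        spec <- parsePretreatment(txt)
        expect_identical(formatPretreatment(spec), txt)
    }
    expect_error(parsePretreatment("XX+MC"), "cannot parse")
    expect_error(pretreatmentSpec(list(list(op = "mean_center"),
                                       list(op = "norm2"))), "last")
    expect_error(pretreatmentSpec(list(list(op = "smooth", width = 3L),
                                       list(op = "deriv1", width = 3L))),
                 "at most one")
    expect_error(pretreatmentSpec(list(list(op = "smooth", width = 4L))),
                 "odd")
})

test_that("pipelines compose operators in order with train/test awareness", {
    X <- withr::with_seed(12, matrix(rnorm(80), 8))
    spec <- parsePretreatment("N+MC")
    res <- applyPretreatment(X, spec)
    manual <- norm2(X)
    manual <- sweep(manual, 2, colMeans(manual))
    expect_equal(res$X, manual, tolerance = 1e-12)
    ## centered data is unchanged by mean centering
    again <- applyPretreatment(res$X, parsePretreatment("MC"))
    expect_equal(again$X, res$X, tolerance = 1e-12)
    ## test mode reuses training statistics
    Xnew <- withr::with_seed(13, matrix(rnorm(30), 3))
    resNew <- applyPretreatment(Xnew, spec, fitted = res$fitted)
    expect_equal(resNew$X,
                 applyColumnScaler(res$fitted, norm2(Xnew)),
                 tolerance = 1e-12)
    ## row-wise operators are row independent: permuting rows commutes
    spec2 <- parsePretreatment("1D(W=5)+SNV")
    sub <- structure(list(steps = spec2$steps[1:2]),
                     class = "PretreatmentSpec")
    perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
    expect_equal(applyPretreatment(X[perm, ], sub)$X,
                 applyPretreatment(X, sub)$X[perm, ], tolerance = 1e-12)
    ## step errors carry the step index
    expect_error(applyPretreatment(rbind(rep(1, 10)),
                                   parsePretreatment("SNV+MC")),
                 "step 1")
})

test_that("the default screening grid enumerates 78 combinations", {
    grid <- buildPretreatmentGrid()
    expect_identical(length(grid), 78L)
    expect_identical(attr(grid, "count"), 78L)
    ## contains the published winner-style specs
    expect_true("1D(W=15)+MC" %in% names(grid))
    expect_true("N+MC" %in% names(grid))
    expect_true("SM(W=23)+N+MC" %in% names(grid))
    expect_true("WLS+N+MC" %in% names(grid))
    ## derivative-only config with one width: {none,d1,d2} x {none,snv,wls}
    small <- buildPretreatmentGrid(widths = 15L,
        smoothers = c("none", "deriv1", "deriv2"),
        scatter = c("none", "snv", "wls_baseline"),
        normalization = "none")
    expect_identical(length(small), 9L)
    expect_error(buildPretreatmentGrid(smoothers = character(0)),
                 "non-empty")
})
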