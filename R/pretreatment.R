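## Mathematical pretreatments for spectral matrices (rows = samples).
## Row-wise operators (smoothing/derivatives, SNV, WLS baseline, 2-norm)
## are stateless per spectrum; column scalers (mean centering, autoscaling)
## learn their parameters from the training partition only.

.rowOps <- c("smooth", "deriv1", "deriv2", "snv", "wls_baseline", "norm2")
.scalerOps <- c("mean_center", "autoscale")

#' Savitzky-Golay smoothing and derivatives
#'
#' Filters each row by a local least-squares polynomial of order
#' `polyorder` over a sliding window of `width` points; `deriv = k` returns
#' the k-th derivative in per-point units (no wavenumber-spacing scaling;
#' downstream modelling is invariant to that constant after centering).
#' Edge points are handled by evaluating the polynomial fitted within the
#' first/last full window.
#'
#' @param X numeric matrix, one spectrum per row
#' @param width odd window width in points, `>= polyorder + 1`
#' @param polyorder polynomial order (default 2)
#' @param deriv derivative order, 0 (smoothing), 1 or 2
#' @return filtered matrix, same shape
#' @export
savitzkyGolay <- function(X, width, polyorder = 2L, deriv = 0L) {
    X <- .asMatrix(X)
    if (width %% 2L == 0L || width < 3L)
        stop("width must be odd and >= 3", call. = FALSE)
    if (width > ncol(X))
        stop("width (", width, ") exceeds the number of variables (",
             ncol(X), ")", call. = FALSE)
    if (width < polyorder + 1L)
        stop("width must be >= polyorder + 1", call. = FALSE)
    if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2", call. = FALSE)
    t(apply(X, 1L, function(r)
        signal::sgolayfilt(r, p = polyorder, n = width, m = deriv, ts = 1)))
}

#' Standard normal variate scatter correction
#'
#' Centers every spectrum to mean 0 and scales it to unit sample standard
#' deviation (denominator n - 1).
#'
#' @param X numeric matrix, one spectrum per row
#' @return transformed matrix
#' @export
snv <- function(X) {
    X <- .asMatrix(X)
    mu <- rowMeans(X)
    s <- apply(X, 1L, sd)
    if (any(s == 0))
        stop("constant spectrum (zero SD) in row(s): ",
             paste(.rowIds(X, s == 0), collapse = ", "), call. = FALSE)
    (X - mu) / s
}

#' 2-norm normalization
#'
#' Divides each spectrum by its Euclidean norm.
#'
#' @param X numeric matrix, one spectrum per row
#' @return matrix with unit-norm rows
#' @export
norm2 <- function(X) {
    X <- .asMatrix(X)
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0))
        stop("zero spectrum in row(s): ",
             paste(.rowIds(X, nrm == 0), collapse = ", "), call. = FALSE)
    X / nrm
}

#' Weighted least squares baseline removal
#'
#' For each spectrum, iteratively fits a polynomial baseline of the given
#' order by weighted least squares, down-weighting points lying above the
#' current baseline (weight `eps` above, 1 below) so that peaks do not pull
#' the baseline up; iteration stops when the weight vector changes by less
#' than `tol` (max-abs) or after `maxIter` passes. Returns the spectrum
#' minus its converged baseline.
#'
#' @param X numeric matrix, one spectrum per row
#' @param order polynomial order of the baseline (default 2)
#' @param maxIter maximum number of reweighting passes (default 100)
#' @param tol convergence tolerance on the weight vector (default 1e-6)
#' @param eps weight given to points above the baseline (default 0.01)
#' @return baseline-corrected matrix
#' @export
wlsBaseline <- function(X, order = 2L, maxIter = 100L, tol = 1e-6,
                        eps = 0.01) {
    X <- .asMatrix(X)
    if (order < 0L) stop("order must be >= 0", call. = FALSE)
    if (order >= ncol(X))
        stop("baseline order must be below the number of variables",
             call. = FALSE)
    if (maxIter < 1L) stop("maxIter must be >= 1", call. = FALSE)
    p <- ncol(X)
    u <- seq(-1, 1, length.out = p)
    B <- cbind(rep(1, p), if (order > 0L) stats::poly(u, degree = order))
    t(apply(X, 1L, function(r) {
        w <- rep(1, p)
        for (it in seq_len(maxIter)) {
            fit <- lm.wfit(B, r, w)
            base <- drop(B %*% fit$coefficients)
            wNew <- ifelse(r > base, eps, 1)
            if (max(abs(wNew - w)) < tol) break
            w <- wNew
        }
        r - base
    }))
}

#' Fit a column scaler on training data
#'
#' `mean_center` learns training column means; `autoscale` additionally
#' learns training column standard deviations. Constant training columns
#' receive scale 1 with a warning (binary covariates can be constant inside
#' small cross-validation folds).
#'
#' @param X_train numeric training matrix
#' @param mode `"mean_center"` or `"autoscale"`
#' @return an object of class `"columnScaler"` for [applyColumnScaler()]
#' @export
fitColumnScaler <- function(X_train, mode = c("mean_center", "autoscale")) {
    mode <- match.arg(mode)
    X_train <- .asMatrix(X_train)
    mu <- colMeans(X_train)
    sc <- rep(1, ncol(X_train))
    if (mode == "autoscale") {
        sc <- apply(X_train, 2L, sd)
        if (any(sc == 0)) {
            warning(sum(sc == 0), " constant training column(s) given",
                    " scale 1", call. = FALSE)
            sc[sc == 0] <- 1
        }
    }
    structure(list(mode = mode, center = mu, scale = sc),
              class = "columnScaler")
}

#' Apply a fitted column scaler
#'
#' @param f object returned by [fitColumnScaler()]
#' @param X matrix with the same variables as the training matrix
#' @return scaled matrix
#' @export
applyColumnScaler <- function(f, X) {
    if (!inherits(f, "columnScaler"))
        stop("scaler has not been fitted; call fitColumnScaler() first",
             call. = FALSE)
    X <- .asMatrix(X)
    if (ncol(X) != length(f$center))
        stop("matrix has ", ncol(X), " columns; scaler was fitted on ",
             length(f$center), call. = FALSE)
    sweep(sweep(X, 2L, f$center, "-"), 2L, f$scale, "/")
}

.asMatrix <- function(X) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    X
}

.rowIds <- function(X, which) {
    rn <- rownames(X)
    if (is.null(rn)) which(which) else rn[which]
}

## ---- PretreatmentSpec: ordered step list with a printable DSL -----------

#' Create a pretreatment specification
#'
#' A `PretreatmentSpec` is an ordered list of operator steps. At most one
#' smoothing/derivative step may appear; `mean_center` and `autoscale` are
#' mutually exclusive and must come last. The canonical operator order is
#' smoothing/derivative, then scatter/baseline correction (SNV or WLS),
#' then 2-norm normalization, then centering -- the conventional order in
#' NIR chemometrics.
#'
#' @param steps list of steps; each step is `list(op = <name>, ...)` with
#'   operator-specific parameters (`width`, `polyorder` for the
#'   Savitzky-Golay family; `order` for `wls_baseline`)
#' @return object of class `"PretreatmentSpec"`
#' @seealso [parsePretreatment()], [formatPretreatment()],
#'   [applyPretreatment()], [buildPretreatmentGrid()]
#' @export
pretreatmentSpec <- function(steps) {
    ops <- vapply(steps, function(s) s$op, character(1L))
    known <- c(.rowOps, .scalerOps)
    if (!all(ops %in% known))
        stop("unknown operator(s): ",
             paste(setdiff(ops, known), collapse = ", "), call. = FALSE)
    if (sum(ops %in% c("smooth", "deriv1", "deriv2")) > 1L)
        stop("at most one smoothing/derivative step allowed", call. = FALSE)
    nsc <- sum(ops %in% .scalerOps)
    if (nsc > 1L)
        stop("mean_center and autoscale are mutually exclusive",
             call. = FALSE)
    if (nsc == 1L && !ops[length(ops)] %in% .scalerOps)
        stop("the column scaler must be the last step", call. = FALSE)
    for (s in steps)
        if (s$op %in% c("smooth", "deriv1", "deriv2")) {
            if (is.null(s$width) || s$width %% 2L == 0L || s$width < 3L)
                stop("window width must be odd and >= 3", call. = FALSE)
        }
    structure(list(steps = steps), class = "PretreatmentSpec")
}

.stepToken <- function(s) {
    switch(s$op,
        smooth = sprintf("SM(W=%d)", s$width),
        deriv1 = sprintf("1D(W=%d)", s$width),
        deriv2 = sprintf("2D(W=%d)", s$width),
        snv = "SNV",
        wls_baseline = "WLS",
        norm2 = "N",
        mean_center = "MC",
        autoscale = "AS")
}

#' Print a pretreatment specification in the compact table notation
#'
#' Produces strings such as `"SM(W=23)+N+MC"`, `"1D(W=15)+MC"` or
#' `"WLS+N+MC"`; [parsePretreatment()] inverts this exactly. An empty spec
#' prints as `"raw"`.
#'
#' @param spec a `PretreatmentSpec`
#' @return single character string
#' @export
formatPretreatment <- function(spec) {
    if (!length(spec$steps)) return("raw")
    paste(vapply(spec$steps, .stepToken, character(1L)), collapse = "+")
}

#' @export
print.PretreatmentSpec <- function(x, ...) {
    cat("<PretreatmentSpec>", formatPretreatment(x), "\n")
    invisible(x)
}

#' Parse the compact pretreatment notation
#'
#' @param text string such as `"1D(W=15)+MC"`; `"raw"` gives an empty spec
#' @param polyorder polynomial order attached to Savitzky-Golay steps
#' @return a `PretreatmentSpec`
#' @export
parsePretreatment <- function(text, polyorder = 2L) {
    text <- trimws(text)
    if (text == "" || tolower(text) == "raw")
        return(pretreatmentSpec(list()))
    toks <- strsplit(text, "+", fixed = TRUE)[[1L]]
    steps <- lapply(toks, function(tk) {
        tk <- trimws(tk)
        mw <- regmatches(tk, regexec("^(SM|1D|2D)\\(W=([0-9]+)\\)$", tk))[[1L]]
        if (length(mw)) {
            op <- c(SM = "smooth", `1D` = "deriv1", `2D` = "deriv2")[[mw[2L]]]
            return(list(op = op, width = as.integer(mw[3L]),
                        polyorder = polyorder))
        }
        op <- switch(tk, SNV = "snv", WLS = "wls_baseline", N = "norm2",
                     MC = "mean_center", AS = "autoscale",
                     stop("cannot parse pretreatment token '", tk, "'",
                          call. = FALSE))
        list(op = op)
    })
    pretreatmentSpec(steps)
}

#' Apply a pretreatment pipeline
#'
#' Row-wise operators are applied statelessly in the listed order. A final
#' column scaler is fitted on `X` when `fitted` is `NULL` (training mode)
#' and re-applied with its stored parameters otherwise (test mode), so no
#' column statistic ever leaks from test data.
#'
#' @param X numeric matrix, one spectrum/sample per row
#' @param spec a `PretreatmentSpec`
#' @param fitted `NULL`, or the `fitted` element returned by a previous
#'   training-mode call
#' @return `list(X = transformed matrix, fitted = fitted state or NULL)`
#' @export
applyPretreatment <- function(X, spec, fitted = NULL) {
    X <- .asMatrix(X)
    scalerOut <- fitted
    for (i in seq_along(spec$steps)) {
        s <- spec$steps[[i]]
        X <- tryCatch(switch(s$op,
            smooth = savitzkyGolay(X, s$width, s$polyorder %||% 2L, 0L),
            deriv1 = savitzkyGolay(X, s$width, s$polyorder %||% 2L, 1L),
            deriv2 = savitzkyGolay(X, s$width,
                                   max(s$polyorder %||% 2L, 2L), 2L),
            snv = snv(X),
            wls_baseline = wlsBaseline(X, s$order %||% 2L),
            norm2 = norm2(X),
            mean_center = ,
            autoscale = {
                if (is.null(scalerOut))
                    scalerOut <- fitColumnScaler(X, s$op)
                applyColumnScaler(scalerOut, X)
            }),
            error = function(e) stop("pretreatment step ", i, " (",
                s$op, "): ", conditionMessage(e), call. = FALSE))
    }
    list(X = X, fitted = scalerOut)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate the pretreatment screening grid
#'
#' Builds the deterministic Cartesian grid
#' \{none | smooth(W) | deriv1(W) | deriv2(W)\} x \{none | SNV | WLS\} x
#' \{none | 2-norm\}, each combination followed by mean centering. With the
#' default width set \{3, 7, 15, 23\} this yields (1 + 3 x 4) x 3 x 2 = 78
#' combinations. Duplicate-equivalent specs are removed.
#'
#' @param widths Savitzky-Golay window widths to screen
#' @param smoothers subset of `c("none", "smooth", "deriv1", "deriv2")`
#' @param scatter subset of `c("none", "snv", "wls_baseline")`
#' @param normalization subset of `c("none", "norm2")`
#' @param scaler final column scaler, `"mean_center"` (default) or
#'   `"autoscale"`
#' @return named list of `PretreatmentSpec` objects (names are the compact
#'   notation); attribute `"count"` holds the combination count
#' @export
buildPretreatmentGrid <- function(widths = c(3L, 7L, 15L, 23L),
        smoothers = c("none", "smooth", "deriv1", "deriv2"),
        scatter = c("none", "snv", "wls_baseline"),
        normalization = c("none", "norm2"),
        scaler = "mean_center") {
    if (!length(smoothers) || !length(scatter) || !length(normalization))
        stop("option lists must be non-empty", call. = FALSE)
    specs <- list()
    for (sm in smoothers) {
        smSteps <- if (sm == "none") list(list()) else
            lapply(widths, function(w) list(list(op = sm, width = w)))
        if (sm == "none") smSteps <- list(list())
        for (st in smSteps) for (sc in scatter) for (nm in normalization) {
            steps <- st
            if (sc != "none") steps <- c(steps, list(list(op = sc)))
            if (nm != "none") steps <- c(steps, list(list(op = nm)))
            steps <- c(steps, list(list(op = scaler)))
            steps <- Filter(length, steps)
            spec <- pretreatmentSpec(steps)
            specs[[formatPretreatment(spec)]] <- spec
        }
    }
    attr(specs, "count") <- length(specs)
    specs
}
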