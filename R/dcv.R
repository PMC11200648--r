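#' Configuration of a repeated double cross-validation run
#'
#' Defaults follow the study design: 10 inner segments (hyperparameter
#' selection), 20 outer segments (validation), 50 repetitions with
#' re-randomized splits, summarized as mean +/- SD over repetitions.
#'
#' @param innerSegments inner-loop segment count (>= 2)
#' @param outerSegments outer-loop segment count (>= 2)
#' @param repetitions number of repetitions (>= 1)
#' @param seed master seed; one child seed is spawned per repetition so a
#'   single repetition is reproducible in isolation
#' @param aMax default latent-variable ceiling used by the convenience
#'   builders (truncated by training rank at fit time)
#' @param priors LDA priors mode, `"equal"` or `"proportional"`
#' @return object of class `"DCVConfig"`
#' @export
dcvConfig <- function(innerSegments = 10L, outerSegments = 20L,
                      repetitions = 50L, seed = 1L, aMax = 10L,
                      priors = "equal") {
    stopifnot(innerSegments >= 2L, outerSegments >= 2L, repetitions >= 1L)
    structure(list(innerSegments = as.integer(innerSegments),
                   outerSegments = as.integer(outerSegments),
                   repetitions = as.integer(repetitions),
                   seed = as.integer(seed), aMax = as.integer(aMax),
                   priors = priors),
              class = "DCVConfig")
}

#' @export
print.DCVConfig <- function(x, ...) {
    cat(sprintf("<DCVConfig> inner %d / outer %d segments, %d repetitions, seed %d\n",
                x$innerSegments, x$outerSegments, x$repetitions, x$seed))
    invisible(x)
}

#' Random segment partition with a class constraint
#'
#' Partitions `n` samples into `k` segments of near-equal size (sizes
#' differ by at most one) uniformly at random. The draw is repeated (up to
#' `maxTries` times) until every training complement -- the samples outside
#' each single segment -- contains both classes; an unsatisfiable
#' constraint (e.g. a single-member class with singleton segments) raises
#' an error.
#'
#' @param n number of samples
#' @param k number of segments (`k <= n`)
#' @param labels binary class labels, length `n`
#' @param seed integer seed; the partition is deterministic given the seed
#' @param maxTries bound on redraws (default 100)
#' @return integer vector of segment indices in `1..k`
#' @export
makePartition <- function(n, k, labels, seed, maxTries = 100L) {
    stopifnot(k <= n, length(labels) == n)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    nPos <- sum(labels == 1L); nNeg <- length(labels) - nPos
    withr::with_seed(seed, {
        for (try in seq_len(maxTries)) {
            part <- sample(rep.int(seq_len(k), sizes))
            ## every training complement (all but one segment) must keep
            ## both classes: no single segment may hold a whole class
            posPer <- tabulate(part[labels == 1L], k)
            negPer <- tabulate(part[labels == 0L], k)
            if (max(posPer) < nPos && max(negPer) < nNeg)
                return(part)
        }
    })
    stop("cannot draw a partition whose every training complement ",
         "contains both classes (class too small for k = ", k, ")",
         call. = FALSE)
}

.nrows <- function(X) if (is.list(X)) nrow(X[[1L]]) else nrow(X)
.rowsub <- function(X, idx) {
    if (is.list(X)) lapply(X, function(b) b[idx, , drop = FALSE])
    else X[idx, , drop = FALSE]
}

#' Inner-loop hyperparameter selection
#'
#' Cross-validates every candidate hyperparameter of the builder inside
#' the given (outer-training) data, pools the inner held-out label
#' predictions, and returns the candidate with the highest inner NER.
#' Ties break to the least complex candidate (fewest latent variables);
#' the builder's candidate list is ordered by complexity.
#'
#' @param X predictor matrix, or list of block matrices
#' @param y binary labels
#' @param builder a model builder, see [plsLdaBuilder()]
#' @param innerSegments number of inner CV segments
#' @param seed partition seed
#' @return `list(best = candidate, ner = inner NER vector)`
#' @export
innerSelect <- function(X, y, builder, innerSegments, seed) {
    cand <- builder$candidates
    if (!length(cand)) stop("no candidates to select from", call. = FALSE)
    if (length(cand) == 1L)
        return(list(best = cand[[1L]], ner = NA_real_))
    n <- .nrows(X)
    part <- makePartition(n, min(innerSegments, n), y, seed)
    pred <- matrix(NA_integer_, n, length(cand))
    for (f in seq_len(max(part))) {
        tr <- part != f; te <- part == f
        Xtr <- .rowsub(X, tr); Xte <- .rowsub(X, te)
        if (!is.null(builder$pathFit)) {
            pm <- tryCatch(builder$pathFit(Xtr, y[tr]),
                           error = function(e) NULL)
            if (!is.null(pm))
                pred[te, ] <- builder$pathClassify(pm, Xte)
        } else {
            for (j in seq_along(cand)) {
                fit <- tryCatch(builder$fit(Xtr, y[tr], cand[[j]]),
                                error = function(e) NULL)
                if (!is.null(fit))
                    pred[te, j] <- builder$classify(fit, Xte)
            }
        }
    }
    ner <- apply(pred, 2L, function(p) {
        if (anyNA(p)) return(NA_real_)
        unname(spSeNer(tn = sum(p == 0L & y == 0L),
                       fp = sum(p == 1L & y == 0L),
                       fn = sum(p == 0L & y == 1L),
                       tp = sum(p == 1L & y == 1L))["NER"])
    })
    if (all(is.na(ner)))
        stop("all candidate hyperparameters failed in the inner loop",
             call. = FALSE)
    list(best = cand[[which.max(ner)]], ner = ner)
}

#' Repeated double cross-validation
#'
#' For each repetition: draw an outer partition; for each outer fold,
#' select hyperparameters by inner cross-validation within the outer
#' training set, fit the model there (all learned parameters -- centering
#' statistics, latent-variable count, LDA threshold -- strictly inside the
#' outer training data), and predict the held-out segment. The pooled
#' outer predictions of a repetition give that repetition's Sp, Se, NER
#' and AUROC; results are summarized as mean +/- SD over repetitions.
#'
#' @param X predictor matrix (rows = samples), or a list of block matrices
#'   for multi-block builders
#' @param y binary labels (1 = GDM)
#' @param builder a model builder, see [plsLdaBuilder()],
#'   [soplsLdaBuilder()], [ruleBuilder()]
#' @param cfg a [dcvConfig()]
#' @return a [DCVResult-class]
#' @export
dcvRun <- function(X, y, builder, cfg = dcvConfig()) {
    y <- as.integer(y)
    n <- .nrows(X)
    stopifnot(length(y) == n)
    reps <- cfg$repetitions
    children <- withr::with_seed(cfg$seed,
        sample.int(.Machine$integer.max - 1L, reps))
    met <- data.frame(repetition = seq_len(reps), Sp = NA_real_,
                      Se = NA_real_, NER = NA_real_, AUROC = NA_real_)
    scoresL <- vector("list", reps); labelsL <- vector("list", reps)
    logRows <- vector("list", reps)
    vipSum <- NULL; vipModels <- 0L
    for (r in seq_len(reps)) {
        seeds <- withr::with_seed(children[r],
            sample.int(.Machine$integer.max - 1L,
                       cfg$outerSegments + 1L))
        part <- makePartition(n, cfg$outerSegments, y, seeds[1L])
        sc <- numeric(n); lb <- integer(n)
        sel <- character(cfg$outerSegments)
        for (f in seq_len(cfg$outerSegments)) {
            tr <- part != f; te <- part == f
            Xtr <- .rowsub(X, tr); Xte <- .rowsub(X, te)
            pick <- innerSelect(Xtr, y[tr], builder, cfg$innerSegments,
                                seeds[f + 1L])
            fit <- builder$fit(Xtr, y[tr], pick$best)
            sc[te] <- builder$score(fit, Xte)
            lb[te] <- builder$classify(fit, Xte)
            sel[f] <- paste(unlist(pick$best), collapse = "/")
            if (!is.null(builder$vip)) {
                v <- builder$vip(fit)
                vipSum <- if (is.null(vipSum)) v else vipSum + v
                vipModels <- vipModels + 1L
            }
        }
        m <- spSeNer(tn = sum(lb == 0L & y == 0L),
                     fp = sum(lb == 1L & y == 0L),
                     fn = sum(lb == 0L & y == 1L),
                     tp = sum(lb == 1L & y == 1L))
        met$Sp[r] <- m["Sp"]; met$Se[r] <- m["Se"]; met$NER[r] <- m["NER"]
        met$AUROC[r] <- auroc(sc, y)
        scoresL[[r]] <- sc; labelsL[[r]] <- lb
        logRows[[r]] <- data.frame(repetition = r,
                                   fold = seq_len(cfg$outerSegments),
                                   selected = sel)
    }
    new("DCVResult", metrics = met, scores = scoresL, labels = labelsL,
        truth = y, log = do.call(rbind, logRows), vipSum = vipSum,
        vipModels = vipModels, config = cfg)
}

#' Summarize a DCV result as mean +/- SD over repetitions
#'
#' @param res a [DCVResult-class]
#' @return one-row data.frame with `*_mean` and `*_sd` columns for Sp, Se,
#'   NER and AUROC
#' @export
dcvSummary <- function(res) {
    m <- res@metrics
    data.frame(Sp_mean = mean(m$Sp), Sp_sd = sd(m$Sp),
               Se_mean = mean(m$Se), Se_sd = sd(m$Se),
               NER_mean = mean(m$NER), NER_sd = sd(m$NER),
               AUROC_mean = mean(m$AUROC), AUROC_sd = sd(m$AUROC))
}

setMethod("show", "DCVResult", function(object) {
    s <- dcvSummary(object)
    cat(sprintf("DCVResult: %d repetitions\n", nrow(object@metrics)))
    cat(sprintf("  NER   %.4f +/- %.4f\n", s$NER_mean, s$NER_sd))
    cat(sprintf("  Sp    %.4f +/- %.4f\n", s$Sp_mean, s$Sp_sd))
    cat(sprintf("  Se    %.4f +/- %.4f\n", s$Se_mean, s$Se_sd))
    cat(sprintf("  AUROC %.4f +/- %.4f\n", s$AUROC_mean, s$AUROC_sd))
})

#' Average VIP vector accumulated across all outer-fold models
#'
#' @param res a [DCVResult-class] produced by a builder exposing VIP
#' @return numeric vector, or `NULL` when the builder has no VIP
#' @export
dcvAverageVip <- function(res) {
    if (is.null(res@vipSum) || res@vipModels == 0L) return(NULL)
    res@vipSum / res@vipModels
}

## ---- model builders ------------------------------------------------------

#' Model builder: single-block PLS-LDA
#'
#' Builders bundle a candidate hyperparameter list with fit/score/classify
#' closures for [dcvRun()]. The PLS-LDA builder screens the latent-variable
#' count `A = 1..aMax` (ordered, so inner-loop ties resolve to the fewest
#' components) and exposes a fast path that fits one NIPALS model at
#' `aMax` and classifies along the nested component path.
#'
#' @param aMax latent-variable ceiling (truncated by training rank)
#' @param priors LDA priors mode
#' @param autoscale scale predictor columns by training SDs before the PLS
#'   fit (used for covariate blocks; spectral blocks are mean-centered
#'   inside the PLS fit itself)
#' @return a builder list for [dcvRun()]
#' @export
plsLdaBuilder <- function(aMax = 10L, priors = "equal",
                          autoscale = FALSE) {
    prep <- function(X) if (autoscale) fitColumnScaler(X, "autoscale")
                        else NULL
    list(
        candidates = as.list(seq_len(aMax)),
        fit = function(X, y, A) {
            sc <- prep(X)
            if (!is.null(sc)) X <- applyColumnScaler(sc, X)
            core <- .plsFitCore(X, as.numeric(y), A)
            if (core$a == 0L) stop("null PLS model")
            yhat <- .corePredict(core, X)
            y <- as.integer(y)
            lda <- .ldaCore(yhat, y == 0L, y == 1L, sum(y == 0L),
                           sum(y == 1L),
                           .priorLogRatio(priors, sum(y == 0L),
                                          sum(y == 1L)))
            if (is.null(lda)) stop("degenerate separation")
            list(core = core, lda = lda, scaler = sc)
        },
        score = function(fit, X) {
            if (!is.null(fit$scaler)) X <- applyColumnScaler(fit$scaler, X)
            .corePredict(fit$core, X)
        },
        classify = function(fit, X) {
            if (!is.null(fit$scaler)) X <- applyColumnScaler(fit$scaler, X)
            .coreClassify(fit$lda$up, fit$lda$thr, .corePredict(fit$core, X))
        },
        pathFit = function(X, y) {
            sc <- prep(X)
            if (!is.null(sc)) X <- applyColumnScaler(sc, X)
            core <- .plsFitCore(X, as.numeric(y), aMax)
            if (core$a == 0L) stop("null PLS model")
            y <- as.integer(y)
            lda <- .ldaPathCore(.coreFittedPath(core), y,
                .priorLogRatio(priors, sum(y == 0L), sum(y == 1L)))
            list(core = core, lda = lda, scaler = sc)
        },
        pathClassify = function(pm, X) {
            if (!is.null(pm$scaler)) X <- applyColumnScaler(pm$scaler, X)
            core <- pm$core
            offs <- core$ym - drop(crossprod(core$xm, core$coefPath))
            Yhat <- .asMatrix(X) %*% core$coefPath
            Yhat <- sweep(Yhat, 2L, offs, "+")
            out <- matrix(NA_integer_, nrow(Yhat), aMax)
            for (a in seq_len(aMax)) {
                aa <- min(a, core$a)   # rank-truncated: nested model
                if (pm$lda$valid[aa])
                    out[, a] <- .coreClassify(pm$lda$up[aa],
                                              pm$lda$thr[aa], Yhat[, aa])
            }
            out
        },
        vip = function(fit) .coreVip(fit$core)
    )
}

#' Model builder: two-block SO-PLS-LDA
#'
#' Screens the exhaustive grid `A1 = 1..a1Max` x `A2 = 0..a2Max` (ordered
#' by total components, then by `A1`, so ties resolve to the smallest
#' `A1 + A2`, then smallest `A1`). `dcvRun()` must be given
#' `X = list(X1, X2)`.
#'
#' @param a1Max,a2Max per-block latent-variable ceilings
#' @param priors LDA priors mode
#' @param autoscale2 autoscale the second block on training data (the
#'   usual treatment for clinical covariate blocks)
#' @return a builder list for [dcvRun()]
#' @export
soplsLdaBuilder <- function(a1Max = 5L, a2Max = 5L, priors = "equal",
                            autoscale2 = TRUE) {
    grid <- expand.grid(A1 = seq_len(a1Max), A2 = 0:a2Max)
    grid <- grid[order(grid$A1 + grid$A2, grid$A1), ]
    list(
        candidates = lapply(seq_len(nrow(grid)), function(i)
            c(A1 = grid$A1[i], A2 = grid$A2[i])),
        fit = function(X, y, hp) {
            sc <- if (autoscale2) fitColumnScaler(X[[2L]], "autoscale")
                  else NULL
            X2 <- if (is.null(sc)) X[[2L]] else applyColumnScaler(sc, X[[2L]])
            f <- soplsFit(X[[1L]], X2, y, A1 = hp[["A1"]], A2 = hp[["A2"]],
                          priors = priors, quiet = TRUE)
            f$scaler2 <- sc
            f
        },
        score = function(fit, X) {
            X2 <- if (is.null(fit$scaler2)) X[[2L]]
                  else applyColumnScaler(fit$scaler2, X[[2L]])
            soplsPredict(fit$model, X[[1L]], X2)
        },
        classify = function(fit, X) {
            X2 <- if (is.null(fit$scaler2)) X[[2L]]
                  else applyColumnScaler(fit$scaler2, X[[2L]])
            ldaClassify(fit$lda, soplsPredict(fit$model, X[[1L]], X2))
        },
        pathFit = NULL, pathClassify = NULL,
        vip = function(fit) {
            v <- vipScores(fit$model)
            c(v$block1, v$block2)
        }
    )
}

#' Model builder: deterministic single-variable rule
#'
#' Predicts GDM iff the given (binary) variable is positive. The rule has
#' no trainable parameters, so every DCV repetition reproduces the same
#' cohort-level confusion counts and the repetition SD of every figure of
#' merit is exactly zero.
#'
#' @param column index of the rule variable
#' @return a builder list for [dcvRun()]
#' @export
ruleBuilder <- function(column = 1L) {
    list(
        candidates = list(NULL),
        fit = function(X, y, hp) list(),
        score = function(fit, X) as.numeric(X[, column]),
        classify = function(fit, X) as.integer(X[, column] > 0.5),
        pathFit = NULL, pathClassify = NULL, vip = NULL
    )
}
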