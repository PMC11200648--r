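## Small in-code fixtures shared across test files.

toySpectrumSet <- function(nSubjects = 4L, replicates = 2L, p = 6L,
                           unit = "reflectance", seed = 42L) {
    wn <- seq(5000, by = -2, length.out = p)
    n <- nSubjects * replicates
    vals <- withr::with_seed(seed, matrix(runif(n * p, 0.2, 0.9), n, p))
    meta <- data.frame(
        record_id = sprintf("s%02d_r%d", rep(seq_len(nSubjects),
                                             each = replicates),
                            rep(seq_len(replicates), nSubjects)),
        subject_id = sprintf("s%02d", rep(seq_len(nSubjects),
                                          each = replicates)),
        replicate = rep(seq_len(replicates), nSubjects),
        label = rep(rep(c(0L, 1L), length.out = nSubjects),
                    each = replicates))
    SpectrumSet(wn, vals, meta, unit = unit)
}

## linearly separable two-class data with signal on the first variable
separableData <- function(n0 = 12L, n1 = 8L, p = 5L, gap = 4,
                          seed = 11L) {
    withr::with_seed(seed, {
        X <- matrix(rnorm((n0 + n1) * p), n0 + n1, p)
        y <- rep(c(0L, 1L), c(n0, n1))
        X[, 1L] <- X[, 1L] * 0.3 + y * gap
        list(X = X, y = y)
    })
}

## full-span axis that contains the 7600 and 5100 boundary points
fullAxisSet <- function(spacing = 100, nRecords = 3L, seed = 5L) {
    wn <- seq(10500, 4000, by = -spacing)
    vals <- withr::with_seed(seed,
        matrix(runif(nRecords * length(wn), 0.1, 1), nRecords))
    meta <- data.frame(record_id = paste0("r", seq_len(nRecords)),
                       subject_id = paste0("s", seq_len(nRecords)),
                       replicate = 1L,
                       label = rep(c(0L, 1L), length.out = nRecords))
    SpectrumSet(wn, vals, meta, unit = "absorbance")
}
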