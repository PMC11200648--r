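## Synthetic cohort generator. Emulates the statistical structure the
## pipeline assumes -- two-class serum-like NIR spectra with instrumental
## replicates and region-dependent noise, plus a clinical covariate table
## with per-class frequencies -- so every stage is testable without any
## deposited data. All choices are generator parameters, not claims about
## the chemistry of real serum.

.defaultBands <- function() {
    ## approximate serum NIR features: broad water bands near 6900 and
    ## 5150 cm-1, protein N-H/C-H combinations near 4600, CH combination
    ## bands near 4350/4260, weak overtones at high wavenumber.
    ## jitterMult scales the subject-level amplitude jitter per band:
    ## water bands vary several-fold more between samples (temperature /
    ## hydration sensitivity) than the solute bands do, which is the main
    ## label-independent nuisance in real serum spectra
    data.frame(
        center    = c(10100, 8700, 6900, 5900, 5150, 4600, 4350, 4260),
        width     = c(  350,  280,  280,  220,  120,  120,   80,   60),
        amplitude = c(0.030, 0.060, 0.55, 0.10, 0.85, 0.30, 0.40, 0.35),
        jitterMult = c(   1,    1,    3,    3,    3,    1,    1,    1))
}

.monthNames <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug",
                 "Sep", "Oct", "Nov", "Dec")

.covariateSpec <- function(scenario) {
    if (scenario == "first_trimester") {
        binary <- data.frame(
            name = c("supplement", "hyperemesis", "vaginal_bleeding",
                     "cigarettes", "alcohol", "other_drugs", "prior_gdm",
                     "prior_hypertensive", "prior_preterm", "prior_other",
                     "prior_nonviable", "fertility_problems", "pcos",
                     "pers_insulin_resistance", "pers_thyroid",
                     "pers_asthma", "pers_other", "fam_insulin_resistance",
                     "fam_dm", "fam_hypertension", "fam_hypothyroid",
                     "fam_hyperthyroid", "fam_asthma", "fam_other"),
            p0 = c(43, 18, 6, 23, 36, 9, 1, 3, 3, 7, 14, 10, 17, 2, 3, 4,
                   7, 2, 22, 28, 12, 1, 5, 11) / 67,
            p1 = c(8, 4, 2, 8, 9, 2, 5, 1, 1, 1, 3, 1, 2, 1, 1, 0, 3, 1,
                   10, 9, 5, 2, 0, 2) / 15)
        gaussian <- data.frame(
            name  = c("age", "bmi", "first_period_age"),
            mean0 = c(30, 27.6, 13), sd0 = c(5, 4.0, 1.5),
            mean1 = c(32, 29.7, 13), sd1 = c(7, 4.0, 1.5))
        month <- data.frame(month = .monthNames,
            p0 = c(5, 4, 5, 2, 9, 7, 6, 5, 4, 9, 7, 4) / 67,
            p1 = c(1, 3, 0, 1, 3, 2, 2, 0, 0, 1, 2, 0) / 15)
    } else {
        binary <- data.frame(
            name = c("supplement", "hyperemesis", "vaginal_bleeding",
                     "cigarettes", "alcohol", "other_drugs", "prior_gdm",
                     "prior_hypertensive", "prior_preterm", "prior_other",
                     "prior_nonviable", "fertility_problems", "pcos",
                     "pers_insulin_resistance", "pers_thyroid",
                     "pers_asthma", "pers_other", "fam_insulin_resistance",
                     "fam_dm", "fam_hypertension", "fam_hypothyroid",
                     "fam_hyperthyroid", "fam_asthma", "fam_other"),
            p0 = c(25, 13, 2, 13, 24, 10, 0, 3, 2, 3, 7, 7, 10, 2, 4, 3,
                   4, 3, 14, 19, 7, 2, 4, 5) / 39,
            p1 = c(5, 2, 2, 3, 4, 0, 3, 0, 1, 0, 1, 0, 1, 0, 0, 0, 3, 1,
                   5, 5, 2, 1, 0, 1) / 8)
        gaussian <- data.frame(
            name  = c("age", "bmi", "first_period_age"),
            mean0 = c(29, 27.0, 13), sd0 = c(5, 4.7, 1.5),
            mean1 = c(30, 31.3, 13), sd1 = c(7, 6.5, 1.5))
        month <- data.frame(month = .monthNames,
            p0 = c(1, 3, 5, 2, 5, 4, 6, 5, 1, 4, 2, 1) / 39,
            p1 = c(0, 2, 0, 1, 0, 1, 2, 1, 1, 1, 0, 0) / 8)
    }
    list(binary = binary, gaussian = gaussian, month = month)
}

#' Configuration of a synthetic cohort
#'
#' The two scenarios mirror the cohort sizes of the study design:
#' `"second_trimester"` 39 controls / 8 cases, `"first_trimester"`
#' 67 controls / 15 cases, both with 5 instrumental replicates per sample.
#' Spectra are built as a smooth polynomial baseline plus Gaussian bands;
#' case bands whose center falls inside an effect interval are scaled by
#' `(1 + delta)` (a multiplicative concentration-like effect, default
#' interval 4762-4348 cm-1, delta 0.15). Each sample gets a multiplicative
#' scatter factor and per-subject band-amplitude jitter; each replicate
#' gets additive Gaussian noise whose SD is piecewise constant per region
#' (defaults: R1 10x, R2 3x, R3 1x the base SD), emulating the
#' high/varying/low sequential-noise structure of transflectance serum
#' spectra.
#'
#' @param scenario `"second_trimester"` or `"first_trimester"`
#' @param nControls,nCases class sizes (defaults from the scenario)
#' @param replicates instrumental replicates per sample
#' @param gridSpacing wavenumber grid step in cm-1 (default 2)
#' @param gridHigh,gridLow axis bounds in cm-1
#' @param bands data.frame `center`, `width` (Gaussian SD, cm-1),
#'   `amplitude` (AU) and optional `jitterMult` (per-band multiplier of
#'   `ampJitterSd`; the water bands default to 3, emulating their
#'   temperature/hydration sensitivity)
#' @param effectIntervals data.frame `high`, `low`, `delta`; bands whose
#'   center lies inside get case amplitudes scaled by `1 + delta`
#' @param noiseBaseSd base additive replicate-noise SD in AU
#' @param noiseRegionFactors multipliers `c(R1, R2, R3)` of the base SD
#' @param noiseCorrFraction fraction of the noise variance carried by a
#'   smooth (wavenumber-correlated) component. Real sequential noise shows
#'   up as trace wander, not per-point scatter; a purely white component
#'   would be largely removed by Savitzky-Golay smoothing and replicate
#'   averaging, which real high-wavenumber noise is not
#' @param noiseCorrLength correlation length of the smooth component in
#'   cm-1
#' @param scatterSd SD of the log multiplicative per-sample scatter factor
#' @param ampJitterSd SD of the per-subject relative band-amplitude jitter
#' @param baselineCoef polynomial baseline coefficients (constant, linear,
#'   quadratic on the axis scaled to `[-1, 1]`)
#' @param unit generate `"absorbance"` (default) or `"reflectance"`
#'   (`R = 10^-A` applied after noise, so absorbance conversion recovers
#'   the absorbance data exactly)
#' @param seed generator seed
#' @return object of class `"CohortConfig"`
#' @export
cohortConfig <- function(scenario = c("second_trimester",
                                      "first_trimester"),
                         nControls = NULL, nCases = NULL,
                         replicates = 5L, gridSpacing = 2,
                         gridHigh = 10500, gridLow = 4000,
                         bands = .defaultBands(),
                         effectIntervals = data.frame(high = 4762,
                             low = 4348, delta = 0.15),
                         noiseBaseSd = 0.04,
                         noiseRegionFactors = c(R1 = 10, R2 = 3, R3 = 1),
                         noiseCorrFraction = 0.5, noiseCorrLength = 150,
                         scatterSd = 0.03, ampJitterSd = 0.06,
                         baselineCoef = c(0.40, 0.12, 0.05),
                         unit = c("absorbance", "reflectance"),
                         seed = 1L) {
    scenario <- match.arg(scenario)
    unit <- match.arg(unit)
    if (is.null(nControls))
        nControls <- if (scenario == "second_trimester") 39L else 67L
    if (is.null(nCases))
        nCases <- if (scenario == "second_trimester") 8L else 15L
    stopifnot(all(bands$amplitude >= 0), noiseBaseSd > 0,
              all(noiseRegionFactors > 0), replicates >= 1L)
    structure(list(scenario = scenario, nControls = as.integer(nControls),
                   nCases = as.integer(nCases),
                   replicates = as.integer(replicates),
                   gridSpacing = gridSpacing, gridHigh = gridHigh,
                   gridLow = gridLow, bands = bands,
                   effectIntervals = effectIntervals,
                   noiseBaseSd = noiseBaseSd,
                   noiseRegionFactors = noiseRegionFactors,
                   noiseCorrFraction = noiseCorrFraction,
                   noiseCorrLength = noiseCorrLength,
                   scatterSd = scatterSd, ampJitterSd = ampJitterSd,
                   baselineCoef = baselineCoef, unit = unit,
                   covariates = .covariateSpec(scenario),
                   seed = as.integer(seed)),
              class = "CohortConfig")
}

#' @export
print.CohortConfig <- function(x, ...) {
    cat(sprintf("<CohortConfig> %s: %d controls / %d cases, %d replicates, grid %g cm-1\n",
                x$scenario, x$nControls, x$nCases, x$replicates,
                x$gridSpacing))
    invisible(x)
}

#' Generate a replicate-level synthetic spectral cohort
#'
#' Deterministic given `seed`: identical configuration and seed yield
#' byte-identical output. Controls come first (subjects `C...`), then
#' cases (`G...`).
#'
#' @param cfg a [cohortConfig()]
#' @param seed overrides `cfg$seed` when given
#' @return a [SpectrumSet-class] with `replicates` records per subject
#' @export
generateSpectra <- function(cfg, seed = cfg$seed) {
    wn <- seq(cfg$gridHigh, cfg$gridLow, by = -cfg$gridSpacing)
    p <- length(wn)
    u <- (wn - mean(range(wn))) / (diff(range(wn)) / 2)
    baseline <- cfg$baselineCoef[1L] + cfg$baselineCoef[2L] * u +
        cfg$baselineCoef[3L] * u^2
    bandShapes <- vapply(seq_len(nrow(cfg$bands)), function(b)
        exp(-(wn - cfg$bands$center[b])^2 / (2 * cfg$bands$width[b]^2)),
        numeric(p))
    noiseSd <- cfg$noiseBaseSd * ifelse(wn > 7600,
        cfg$noiseRegionFactors[[1L]],
        ifelse(wn > 5100, cfg$noiseRegionFactors[[2L]],
               cfg$noiseRegionFactors[[3L]]))
    nSub <- cfg$nControls + cfg$nCases
    labels <- rep(c(0L, 1L), c(cfg$nControls, cfg$nCases))
    subj <- c(sprintf("C%03d", seq_len(cfg$nControls)),
              sprintf("G%03d", seq_len(cfg$nCases)))
    ## case amplitude scaling for bands inside effect intervals
    effMult <- rep(1, nrow(cfg$bands))
    for (i in seq_len(nrow(cfg$effectIntervals))) {
        inb <- cfg$bands$center <= cfg$effectIntervals$high[i] &
               cfg$bands$center >= cfg$effectIntervals$low[i]
        effMult[inb] <- effMult[inb] * (1 + cfg$effectIntervals$delta[i])
    }
    ## unit-variance Gaussian smoothing kernel for the correlated noise
    ## component (L2-normalized so filtered white noise keeps SD 1)
    kern <- NULL
    if (cfg$noiseCorrFraction > 0) {
        ksd <- max(cfg$noiseCorrLength / cfg$gridSpacing, 0.5)
        half <- ceiling(3 * ksd)
        kern <- exp(-(seq(-half, half))^2 / (2 * ksd^2))
        kern <- kern / sqrt(sum(kern^2))
    }
    drawNoise <- function() {
        white <- rnorm(p)
        if (is.null(kern)) return(noiseSd * white)
        w2 <- rnorm(p + 2L * length(kern))
        sm <- stats::convolve(w2, kern, type = "filter")
        off <- (length(sm) - p) %/% 2L
        sm <- sm[(off + 1L):(off + p)]
        noiseSd * (sqrt(1 - cfg$noiseCorrFraction) * white +
                   sqrt(cfg$noiseCorrFraction) * sm)
    }
    nrec <- nSub * cfg$replicates
    vals <- matrix(0, nrec, p)
    meta <- data.frame(record_id = character(nrec),
                       subject_id = character(nrec),
                       replicate = integer(nrec), label = integer(nrec))
    withr::with_seed(seed, {
        row <- 0L
        jm <- if (is.null(cfg$bands$jitterMult)) rep(1, nrow(cfg$bands))
              else cfg$bands$jitterMult
        for (i in seq_len(nSub)) {
            amp <- cfg$bands$amplitude *
                (1 + rnorm(nrow(cfg$bands), 0, cfg$ampJitterSd) * jm)
            amp <- pmax(amp, 0)
            if (labels[i] == 1L) amp <- amp * effMult
            scatter <- exp(rnorm(1L, 0, cfg$scatterSd))
            clean <- scatter * (baseline + drop(bandShapes %*% amp))
            for (r in seq_len(cfg$replicates)) {
                row <- row + 1L
                vals[row, ] <- clean + drawNoise()
                meta$record_id[row] <- sprintf("%s_r%d", subj[i], r)
                meta$subject_id[row] <- subj[i]
                meta$replicate[row] <- r
                meta$label[row] <- labels[i]
            }
        }
    })
    if (cfg$unit == "reflectance") vals <- 10^(-vals)
    SpectrumSet(wn, vals, meta, unit = cfg$unit)
}

#' Generate a synthetic clinical covariate table
#'
#' Draws the 28-variable covariate table of the cohort design: 24 binary
#' covariates Bernoulli with per-class frequencies, age / BMI / age at
#' first period Gaussian per class (rounded to the recorded precision),
#' and month of last period categorical with per-class frequencies.
#' Deterministic given `seed`.
#'
#' @param cfg a [cohortConfig()]
#' @param seed overrides `cfg$seed` when given
#' @param n0,n1 class sizes (defaults from the config)
#' @return data.frame with `subject_id`, `label` and 28 covariates
#' @export
generateMedicalTable <- function(cfg, seed = cfg$seed,
                                 n0 = cfg$nControls, n1 = cfg$nCases) {
    cs <- cfg$covariates
    n <- n0 + n1
    labels <- rep(c(0L, 1L), c(n0, n1))
    out <- data.frame(subject_id = c(sprintf("C%03d", seq_len(n0)),
                                     sprintf("G%03d", seq_len(n1))),
                      label = labels)
    withr::with_seed(seed, {
        for (i in seq_len(nrow(cs$gaussian))) {
            g <- cs$gaussian[i, ]
            v <- numeric(n)
            v[labels == 0L] <- rnorm(n0, g$mean0, g$sd0)
            v[labels == 1L] <- rnorm(n1, g$mean1, g$sd1)
            dg <- if (g$name == "bmi") 1L else 0L
            out[[g$name]] <- round(v, dg)
        }
        for (i in seq_len(nrow(cs$binary))) {
            b <- cs$binary[i, ]
            v <- integer(n)
            v[labels == 0L] <- rbinom(n0, 1L, b$p0)
            v[labels == 1L] <- rbinom(n1, 1L, b$p1)
            out[[b$name]] <- v
        }
        pm0 <- cs$month$p0 / sum(cs$month$p0)
        pm1 <- cs$month$p1 / sum(cs$month$p1)
        mo <- character(n)
        mo[labels == 0L] <- sample(cs$month$month, n0, TRUE, pm0)
        mo[labels == 1L] <- sample(cs$month$month, n1, TRUE, pm1)
        out$last_period_month <- factor(mo, levels = cs$month$month)
    })
    out
}

#' Encode a medical table as a numeric model matrix
#'
#' Quantitative variables stay as-is, binary covariates as 0/1, and the
#' month of last period is expanded to 11 indicator columns (January as
#' reference). The result is the covariate block fed (after training-set
#' autoscaling) to the multi-block models.
#'
#' @param med data.frame from [generateMedicalTable()]
#' @return numeric matrix, one row per subject
#' @export
encodeMedicalMatrix <- function(med) {
    keep <- setdiff(colnames(med), c("subject_id", "label",
                                     "last_period_month"))
    m <- as.matrix(med[, keep])
    mo <- med$last_period_month
    dummies <- vapply(levels(mo)[-1L], function(l) as.numeric(mo == l),
                      numeric(nrow(med)))
    out <- cbind(m, dummies)
    rownames(out) <- med$subject_id
    out
}
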