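test_that("the generator is deterministic and respects the noiseless limit", {
    cfg <- cohortConfig("second_trimester", gridSpacing = 50,
                        nControls = 6L, nCases = 3L, replicates = 3L)
    s1 <- generateSpectra(cfg, seed = 4)
    s2 <- generateSpectra(cfg, seed = 4)
    expect_identical(intensityMat(s1), intensityMat(s2))
    expect_false(identical(intensityMat(generateSpectra(cfg, seed = 5)),
                           intensityMat(s1)))
    expect_identical(ncol(s1), 9L * 3L)
    expect_identical(sum(classLabels(s1) == 1L) / 3L, 3)
    ## near-zero replicate noise: replicates of a subject coincide
    cfg0 <- cohortConfig("second_trimester", gridSpacing = 50,
                         nControls = 4L, nCases = 2L, replicates = 3L,
                         noiseBaseSd = 1e-12)
    s0 <- generateSpectra(cfg0, seed = 4)
    m <- intensityMat(s0)
    for (sub in unique(subjectIds(s0))) {
        rows <- m[subjectIds(s0) == sub, , drop = FALSE]
        expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-9)
    }
    ## reflectance mode is the exact inverse transform of absorbance mode
    cfgR <- cohortConfig("second_trimester", gridSpacing = 50,
                         nControls = 4L, nCases = 2L, replicates = 2L,
                         unit = "reflectance")
    cfgA <- cohortConfig("second_trimester", gridSpacing = 50,
                         nControls = 4L, nCases = 2L, replicates = 2L)
    sR <- generateSpectra(cfgR, seed = 6)
    sA <- generateSpectra(cfgA, seed = 6)
    expect_equal(intensityMat(reflectanceToAbsorbance(sR)),
                 intensityMat(sA), tolerance = 1e-12)
})

test_that("replicate noise follows the configured region profile", {
    cfg <- cohortConfig("second_trimester", gridSpacing = 10,
                        nControls = 40L, nCases = 10L, replicates = 4L)
    s <- generateSpectra(cfg, seed = 7)
    m <- intensityMat(s)
    wn <- wavenumbers(s)
    ## noise SD estimated from within-subject replicate deviations
    dev <- do.call(rbind, lapply(unique(subjectIds(s)), function(sub) {
        rows <- m[subjectIds(s) == sub, , drop = FALSE]
        sweep(rows, 2, colMeans(rows))
    }))
    sdByCol <- apply(dev, 2, sd)
    sdR1 <- mean(sdByCol[wn > 7600])
    sdR3 <- mean(sdByCol[wn < 5100])
    ## configured ratio 10:1, matched within 20%
    expect_lt(abs(sdR1 / sdR3 - 10) / 10, 0.2)
})

test_that("exchangeable classes give chance-level downstream performance", {
    cfg <- cohortConfig("second_trimester", gridSpacing = 25,
        effectIntervals = data.frame(high = 4762, low = 4348, delta = 0))
    s <- averageReplicates(generateSpectra(cfg, seed = 8))
    r3 <- extractRange(s, "R3")
    res <- dcvRun(intensityMat(r3), classLabels(r3), plsLdaBuilder(3),
                  dcvConfig(repetitions = 6, seed = 8, aMax = 3))
    m <- res@metrics
    ## one finite cohort carries chance association of SD
    ## ~ sqrt((n+1)/(12 n0 n1)); bound by the larger of that and the
    ## repetition SD
    nullSd <- sqrt((39 + 8 + 1) / (12 * 39 * 8))
    expect_lt(abs(mean(m$NER) - 0.5), 3 * max(sd(m$NER), nullSd))
    expect_lt(abs(mean(m$AUROC) - 0.5), 3 * max(sd(m$AUROC), nullSd))
})

test_that("an effect planted in R1 is recoverable despite R1-level noise", {
    ## strong amplitude effect on the 8700 cm-1 overtone (large, because
    ## R1 carries 0.4 AU replicate noise): R1 models must beat the chance
    ## level of a null model
    ners <- vapply(6:8, function(sd_) {
        cfg <- cohortConfig("second_trimester", gridSpacing = 10,
            effectIntervals = data.frame(high = 9000, low = 8400,
                                         delta = 8))
        s <- averageReplicates(generateSpectra(cfg, seed = sd_))
        r1 <- extractRange(s, "R1")
        res <- dcvRun(intensityMat(r1), classLabels(r1), plsLdaBuilder(5),
                      dcvConfig(repetitions = 5, seed = sd_, aMax = 5))
        mean(res@metrics$NER)
    }, numeric(1))
    expect_gte(sum(ners > 0.65), 2L)
})

test_that("covariate tables reproduce configured frequencies and effects", {
    cfg <- cohortConfig("second_trimester")
    med <- generateMedicalTable(cfg, seed = 9)
    expect_identical(nrow(med), 47L)
    ## 28 variables besides subject_id and label
    expect_identical(ncol(med) - 2L, 28L)
    expect_identical(generateMedicalTable(cfg, seed = 9), med)
    ## a frequency-zero covariate is all zero in that class: prior GDM in
    ## second-trimester controls is 0/39
    expect_identical(sum(med$prior_gdm[med$label == 0L]), 0L)
    ## configured BMI class difference (31.3 - 27.0)
    expect_equal(with(cfg$covariates$gaussian,
                      mean1[name == "bmi"] - mean0[name == "bmi"]), 4.3)
    ## law of large numbers at n = 1e4 per class: within 3 binomial SDs
    big <- generateMedicalTable(cfg, seed = 10, n0 = 10000L, n1 = 10000L)
    for (v in c("fam_dm", "cigarettes", "pcos")) {
        p0 <- cfg$covariates$binary$p0[cfg$covariates$binary$name == v]
        emp <- mean(big[[v]][big$label == 0L])
        expect_lt(abs(emp - p0), 3 * sqrt(p0 * (1 - p0) / 10000) + 1e-12)
    }
    ## encoded matrix: numeric, with 11 month indicator columns
    enc <- encodeMedicalMatrix(med)
    expect_identical(ncol(enc), 27L + 11L)
    expect_true(is.numeric(enc))
    ## prior-GDM rule frequencies reproduce the expected asymptotic NER
    pg <- cfg$covariates$binary[cfg$covariates$binary$name == "prior_gdm", ]
    expect_equal(((1 - pg$p0) + pg$p1) / 2, 0.6875)
})
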