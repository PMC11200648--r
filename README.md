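# gdmnir

Chemometric classification of serum near-infrared (NIR) spectra for
gestational diabetes mellitus (GDM) screening.

Serum NIR spectra (10,500–4000 cm⁻¹, transflectance) carry weak
metabolic information under heavy, region-dependent noise. `gdmnir`
implements the complete workflow used to mine them for a two-class
(GDM vs. normal glucose tolerance, NGT) screening model:

* **Spectral data model** — `SpectrumSet` (a `SummarizedExperiment`)
  with replicate-aware metadata, reflectance→absorbance conversion
  (`A = log₁₀(1/R)`), replicate averaging, and the four canonical
  ranges Full / R1 (10,500–7600) / R2 (7600–5100) / R3 (5100–4000 cm⁻¹).
* **Pretreatments** — Savitzky–Golay smoothing/derivatives, SNV,
  iterative weighted-least-squares baseline removal, 2-norm
  normalization, mean centering and autoscaling, composable through a
  compact notation (`"1D(W=15)+MC"`) and enumerable as a screening grid
  (78 combinations by default).
* **PLS-LDA** — PLS1 regression on the binary-coded response
  (`T = XR`, `ŷ = Tq = Xb`, `b = Rq`; compiled kernel algorithm,
  identical to NIPALS), thresholded by one-dimensional pooled-variance
  LDA: `y_thres = (m₀+m₁)/2 + σ² ln(π₀/π₁)/(m₁−m₀)`.
* **SO-PLS-LDA** — sequential orthogonalized two-block fusion
  (e.g. spectra + 28 clinical covariates):
  `ŷ_SO = X₁b₁ + X₂,orth b₂,orth` with
  `X₂,orth = X₂ − T₁(T₁ᵀT₁)⁻¹T₁ᵀX₂`.
* **Repeated double cross-validation** — 10 inner segments select the
  latent-variable count, 20 outer segments estimate performance, 50
  repetitions with re-randomized splits; everything learned (centering,
  scaling, thresholds, component counts) stays inside the outer-training
  partitions. Reports Sp, Se, NER = (Sp+Se)/2 and AUROC as mean ± SD.
* **VIP relevance** — standard PLS variable importance in projection,
  averaged over all outer-fold models, thresholded at 1, and merged
  into contiguous wavenumber intervals.
* **Synthetic cohorts** — a generator that emulates the study
  conditions (39/8 and 67/15 cohorts, 5 replicates, serum-like bands,
  region-dependent correlated noise, clinical covariate frequencies) so
  the whole pipeline is testable without clinical data.

## Worked example

Generate a synthetic second-trimester cohort (39 NGT / 8 GDM subjects,
5 replicates each) with a class effect confined to the glucose
combination-band region (4762–4348 cm⁻¹), screen a small pretreatment
grid over all four ranges, and report the best model:

```r
library(gdmnir)

cfg <- cohortConfig("second_trimester", gridSpacing = 10)
spectra <- averageReplicates(generateSpectra(cfg, seed = 2))

grid <- buildPretreatmentGrid(widths = 15L,
    smoothers = c("none", "smooth", "deriv1", "deriv2"),
    scatter = c("none", "snv", "wls_baseline"),
    normalization = "none")

scr <- runScreening(spectra, grid,
                    cfg = dcvConfig(repetitions = 10, seed = 2,
                                    aMax = 5))
bestPerRange(scr)[, c("range", "pretreatment", "NER_mean", "NER_sd")]
#>   range    pretreatment  NER_mean     NER_sd
#> 1    R3          SNV+MC 0.7450321 0.03982801
#> 2    R2 1D(W=15)+WLS+MC 0.5102564 0.04563604
#> 3    R1 1D(W=15)+WLS+MC 0.4979167 0.04498644
#> 4  Full              MC 0.4679487 0.01089534
```

The screening ranks R3 — the only range containing the planted effect —
first, with a mean NER (balanced accuracy) of 0.745 ± 0.040 over 10 DCV
repetitions; the noise-dominated R1/R2 sit at chance, and the Full range
pays the dilution penalty for carrying them. The best model's report
adds AUROC, ROC curves and VIP intervals:

```r
rep <- reportBest(scr)
c(rep$aurocMean, rep$aurocSd)
#> [1] 0.80987179 0.01787514
rep$intervals    # relevant wavenumber intervals (average VIP > 1)
#>   high  low n_points
#> 1 5100 5030        8
#> 2 4930 4890        5
#> 3 4810 4810        1
#> 4 4710 4520       20
#> 5 4420 4190       24
#> 6 4090 4090        1
```

The two largest relevant intervals (4710–4520 and 4420–4190 cm⁻¹) sit on
the flanks of the affected bands at 4600 and 4350 cm⁻¹, which is where a
concentration effect shows up after scatter-corrected modelling. Runs are
fully deterministic: identical seed and configuration reproduce these
numbers byte for byte.

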