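---
title: "Chemometric screening of serum NIR spectra: models and methods"
author: "gdmnir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric screening of serum NIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmnir)
```

## The problem

Gestational diabetes mellitus (GDM) is usually diagnosed with an oral
glucose tolerance test, which is slow and unpleasant. Near-infrared (NIR)
spectra of a few microlitres of serum can be acquired in minutes, and the
combination bands of glucose, lipids and proteins between 10,500 and
4000 cm^-1^ carry — weakly, and buried under instrument noise and
scatter — information about the metabolic state of the patient. `gdmnir`
implements the full chemometric workflow needed to turn such spectra into
a validated two-class screening model: pretreatment screening, PLS-LDA and
two-block SO-PLS-LDA classification, repeated double cross-validation
(DCV), figures of merit, and VIP-based variable relevance. A synthetic
cohort generator with the same statistical structure makes every stage
testable without clinical data.

## Data model

A `SpectrumSet` (an extension of `SummarizedExperiment`) stores one
spectral variable per row and one *record* — an instrumental replicate of
one subject's sample — per column. The axis is kept strictly descending
(10,500 → 4000 cm^-1^, instrument convention). The acquisition protocol
this mirrors records five transflectance replicates per sample; replicates
are averaged (`averageReplicates()`) *before* the reflectance fractions
are converted to absorbance `A = log10(1/R)` — the order used in the
protocol itself. The default wavenumber step is 2 cm^-1^ (3251 points for
the full span): the instrument resolution is 4 cm^-1^ but the export grid
is not fixed by it, and all published interval endpoints are even numbers;
the grid is a constructor argument everywhere.

Four canonical ranges are screened: Full (10,500–4000), R1 (10,500–7600,
high noise), R2 (7600–5100, varying noise) and R3 (5100–4000, low noise —
the glucose/CH combination-band region). Bounds are closed on both ends,
so 7600 and 5100 belong to both neighbouring ranges, matching how the
ranges are conventionally quoted.

## Pretreatments

Eight operators are available, composable through `pretreatmentSpec()` and
a compact printable notation (`"1D(W=15)+MC"`):

* **Savitzky–Golay** smoothing and 1st/2nd derivatives (`SM`, `1D`,
  `2D`), polynomial order 2 by default, window width an odd point count.
  Derivatives are reported in per-point units; downstream models are
  invariant to the constant per-Δν factor after centering.
* **SNV** (`SNV`): per-spectrum centering and unit-SD scaling.
* **Weighted least-squares baseline** (`WLS`): per-spectrum polynomial
  baseline (order 2 default) re-fitted with asymmetric weights — 1 below
  the current baseline, 0.01 above — until the weight vector stabilises
  (tolerance 1e-6, at most 100 passes). The asymmetry stops positive
  peaks from pulling the baseline up.
* **2-norm normalization** (`N`), and the final column scalers
  **mean centering** (`MC`) / **autoscaling** (`AS`).

Row-wise operators act on each spectrum independently and carry no
cross-sample state; the column scalers learn their statistics from the
training partition only (`fitColumnScaler()` / `applyColumnScaler()`), and
constant training columns under autoscaling receive scale 1 with a warning
because binary covariates can be constant inside small CV folds.

The canonical order — smoothing/derivative, then scatter/baseline
correction, then normalization, then centering — follows chemometric
convention; the screening grid
(`buildPretreatmentGrid()`) enumerates \{none, SM(W), 1D(W), 2D(W)\} ×
\{none, SNV, WLS\} × \{none, N\}, each followed by MC, over the width set
\{3, 7, 15, 23\}: 78 combinations. The reference workflow this reimplements
reports screening 80 combinations without enumerating them; the 78-spec
default is the closest reconstructable grid and the builder is
configuration-driven, so any other enumeration can be reproduced. Spectral
blocks are mean-centered, clinical covariate blocks autoscaled.

## PLS-LDA

Classification is formulated as regression on a binary-coded response
(1 = GDM, 0 = NGT). PLS1 compresses the centered predictor matrix into
scores `T = Xc R` with maximal covariance with the response; regressing
`y` on the scores gives `yhat = T q = Xc b` with `b = R q`. The
implementation is the kernel form with covariance-vector deflation
(Dayal & MacGregor), which is algebraically identical to NIPALS with
X-deflation for a single response; the compiled kernel (RcppArmadillo) and
a plain-R reference implementation are both shipped and tested against
each other, and against an independent SIMPLS implementation and
full-rank least squares in the test suite.

The real-valued `yhat` is thresholded by one-dimensional two-class LDA
with pooled within-class variance:
`y_thres = (m0 + m1)/2 + s² log(π0/π1)/(m1 − m0)`. Priors default to
*equal* — model selection uses the non-error rate, which weights the
classes equally, and the cohorts are strongly imbalanced — and can be set
to *proportional*. Pooled (equal-variance) LDA is used, which is what
"LDA" denotes in this literature. Exact ties at the threshold go to the
NGT class, deterministically; which side of the threshold means GDM is
recorded explicitly (`orientation`), so a response inversion cannot flip
labels silently.

## SO-PLS-LDA

Two predictor blocks (e.g. NIR spectra and 28 clinical covariates) are
fused sequentially: (1) PLS of `y` on block 1 with `A1` components;
(2) the centered second block is orthogonalized against the block-1
scores, `X2,orth = X2 − T1 (T1'T1)^-1 T1' X2`; (3) PLS of the first-block
residuals `e1 = y − yhat1` on `X2,orth` with `A2` components. Predictions
add the two contributions and LDA is applied to the combined response.
`A2 = 0` reduces exactly to the single-block model, which is the natural
test of whether the second block adds anything. New samples are
orthogonalized through the training projection, using block-1 scores
predicted for the new rows — the standard SO-PLS prediction convention.
Both block orders can be run; they are not equivalent. The per-block
component pair is selected on an exhaustive `A1 × A2` grid inside the
inner CV loop, with ties broken to the smallest `A1 + A2`, then the
smallest `A1` (a global grid is deterministic, unlike sequential
forward selection).

## Repeated double cross-validation

`dcvRun()` nests two loops: the **inner** loop (10 segments) selects the
hyperparameters — the latent-variable count, up to `aMax` (default 10,
truncated by training rank) — by maximising inner NER with ties to the
fewest components; the **outer** loop (20 segments) estimates performance
on samples never used for any fitted quantity: centering statistics,
autoscaling SDs, LDA thresholds and component counts are all learned
strictly inside each outer-training partition (row-wise pretreatment
operators are per-spectrum and carry no such state, so they are applied
once, outside the loops). The whole procedure is repeated 50 times with
re-randomized splits, and every figure of merit is reported as mean ± SD
over repetitions.

Partitions are plain random with near-equal segment sizes (difference at
most one), redrawn until every training complement contains both classes;
with 8 positives and 20 outer segments per-segment stratification is
impossible, so none is attempted. The master seed spawns one child seed
per repetition, so a single repetition is reproducible in isolation; a
given seed yields byte-identical results.

Per repetition, the pooled outer-fold predictions give Sp = TN/(TN+FP),
Se = TP/(TP+FN), NER = (Sp+Se)/2 (balanced accuracy) and AUROC — computed
by the rank/Mann–Whitney formulation with ties counted one-half, which is
exact where trapezoidal integration needs care. AUROC is computed per
repetition on that repetition's pooled outer predictions and then
averaged ± SD, which is why it carries a repetition SD. ROC curves are
vertically averaged on a 101-point false-positive-rate grid with
step-function interpolation and pinned endpoints.

## VIP relevance

For a fitted PLS model the variable importance in projection is the
standard single-response form
`VIP_j = sqrt( p · Σ_a SS_a (w_ja/‖w_a‖)² / Σ_a SS_a )` with
`SS_a = q_a² t_a't_a`; the mean squared VIP equals 1 by construction,
motivating the conventional "average VIP > 1" relevance rule
(strict inequality). VIP vectors are averaged across **all** outer-fold
models of **all** repetitions, each model weighted equally — the averaging
population is otherwise underdetermined, and this choice uses every
validated model exactly once. Relevant variables are reported as
contiguous wavenumber intervals; runs separated by at most 3 unselected
points (configurable) are merged, since reported intervals are "mainly",
not exclusively, composed of relevant variables. For SO-PLS models VIP is
computed per block from that block's sub-model.

## The synthetic cohort generator

`generateSpectra()` builds, per subject, a smooth quadratic baseline plus
Gaussian bands, multiplies the subject's spectrum by a log-normal scatter
factor, and adds per-replicate Gaussian noise whose SD is piecewise
constant per region. The defaults emulate the study conditions this
package is built around:

* cohort sizes 39 controls / 8 cases ("second trimester") or 67/15
  ("first trimester"), 5 replicates per sample;
* a band library sketching serum NIR features (broad water bands near
  6900 and 5150 cm^-1^, protein combinations near 4600, CH combination
  bands near 4350/4260, weak high-wavenumber overtones) — generator
  parameters, not claims about real serum chemistry;
* class effect: bands whose center lies in 4762–4348 cm^-1^ (a glucose
  combination-band region) have case amplitudes scaled by 1 + δ,
  δ = 0.15 — a multiplicative, concentration-like effect;
* between-subject band-amplitude jitter of 6% and 3% multiplicative
  scatter, chosen so that the planted effect yields a balanced accuracy
  in the high-0.8s — the difficulty regime of the cohort study this
  emulates (whose best model reached NER ≈ 0.79), rather than a
  trivially separable toy. The water bands carry a 3× jitter
  multiplier: water dominates serum NIR variability
  (temperature/hydration sensitivity), and this label-independent
  nuisance — which neither replicate averaging nor any row-wise
  pretreatment removes — is what makes ranges diluted with
  water-dominated regions genuinely harder, as observed in practice;
* replicate noise base SD 0.04 AU with region factors 10/3/1
  (R1/R2/R3), split evenly between a white per-point component and a
  smooth component with 150 cm^-1^ correlation length. Both choices
  matter. The magnitude: models built on the high-noise region of real
  serum spectra perform at chance, so R1 noise (0.4 AU per replicate)
  must be large enough to make R1 *unusable*, not merely inconvenient —
  otherwise the Full range, which contains the informative sub-range,
  would never rank below it. The correlation: sequential noise in real
  transflectance spectra appears as trace *wander*, and a purely white
  model would be removed almost entirely by Savitzky–Golay smoothing
  plus replicate averaging; the smooth component survives any row-wise
  pretreatment, producing the range-dilution behaviour the screening
  design exists to detect.

`generateMedicalTable()` draws the 28-variable clinical table (24 binary
covariates with per-class Bernoulli frequencies taken from the cohort
description tables, Gaussian age/BMI/menarche age per class, categorical
month of last period) and `encodeMedicalMatrix()` expands it to a numeric
block for fusion models.

What the generator does **not** emulate: wavenumber-correlated noise,
instrument drift, water-displacement artefacts, nonlinear detector
response, and any real biochemical covariance between clinical covariates
and spectra (covariates and spectra are drawn independently given the
class). Passing recovery tests therefore demonstrates that the pipeline
finds structure of the planted kind at realistic noise — not that real
serum spectra contain such structure.

## Numerical choices and scale of the shipped checks

Component extraction stops when the residual covariance or score norm
falls below `1e-12` relative to the training X sum of squares; requesting
more components than the rank supports truncates with a warning. A
response with zero variance yields an explicit null model (zero
coefficients). Rank-deficient score matrices in the orthogonalization step
fall back to a pseudo-inverse with a warning. Exact threshold ties
classify as NGT; screening-table NER ties are broken by mean AUROC, which
stays informative after the 0/1 label metrics saturate.

The packaged tests and the acceptance script run a reduced replica of the
full design so the whole suite stays desk-sized: synthetic cohorts on a
10 cm^-1^ grid (651 Full-range points), a 12-spec pretreatment grid
(widths fixed at 15), 10 DCV repetitions and `aMax = 5`. These are the
package's own reduced-scale choices; all of them are ordinary arguments,
and the full 2 cm^-1^ / 78-spec / 50-repetition configuration is the
documented default of the exported functions.

## Known limitations

* PLS1 only (binary response); PLS2, kernel and sparse variants are out
  of scope, as are more than two blocks.
* The 80-combination pretreatment enumeration of the reference workflow
  cannot be reconstructed exactly; the default grid has 78.
* DCV estimates internal validity only; nothing here substitutes for an
  external test cohort.
* AUROC-vs-NER model selection can disagree near saturation; selection
  uses NER (with the documented AUROC tie-break) throughout.
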