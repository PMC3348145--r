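---
title: "Nuclear morphometry profiles and weighted-voting expression signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry profiles and weighted-voting expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsig)
```

## The problem

Platinum-based chemotherapy is the standard of care for advanced serous
ovarian carcinoma, but a substantial minority of patients relapse within
six months of their last platinum treatment (the *chemoresistant* class;
the remainder, with a platinum-free interval of at least six months, are
*chemosensitive*). `nucsig` implements an integrated analysis that asks
two questions of a cohort with histology images, gene expression and
clinical follow-up:

1. Can a gene-expression classifier predict platinum response, and does
   its score stratify survival?
2. Do quantitative nuclear-morphology features — summarized per patient
   as a size-binned profile — associate with response and with the
   expression signature?

Everything is exercisable on synthetic cohorts with planted ground
truth, so each stage of the pipeline can be validated end to end
without any external data.

## Nucleus segmentation and measurement

Images are assumed to show dark nuclei on a lighter background
(hematoxylin convention). The per-image chain is:

* **FFT band-pass** (`fft_bandpass`): structures smaller than
  `band_low = 3` px and larger than `band_high = 40` px are suppressed
  with Gaussian low/high-pass transfer functions, each at half power at
  its cutoff. Nuclei in the retained size range (50–500 px², diameters
  roughly 8–25 px) pass essentially untouched while illumination
  gradients and pixel noise are removed. The image is mirror-padded
  before the transform so the periodic extension is continuous.
* **Thresholding** (`preprocess_to_mask`): Otsu's method on the
  filtered image by default. The original workflow verified a manual
  threshold against the slide by eye; a deterministic automatic
  threshold replaces that human step, with a numeric override for users
  who want to reproduce a specific cutoff.
* **Labelling** (`segment_mask`): connected components of the
  8-neighbour pixel graph (corner contact joins), the common default
  for roundish blobs.
* **Measurement** (`measure_regions`): area is the pixel count;
  perimeter is the isothetic crack-boundary length scaled by π/4,
  an estimator that is unbiased for digitized disks (it differs from
  ImageJ's traced-polygon length by a few percent on elongated
  shapes); ellipse axes come from second-order central moments with a
  +1/12 per-pixel variance term (each pixel treated as a unit square),
  which keeps the minor axis positive even for thin regions; convex
  area is the hull of the pixel corners. Circularity
  $4\pi A / P^2$, roundness $4A/(\pi\,\text{major}^2)$ and solidity
  are capped at 1 because discretization can push them slightly above
  it. Single-pixel regions have degenerate moments and are dropped.
* **Gating** (`filter_nuclei`): areas in [50, 500] px² inclusive and
  circularity strictly greater than 0.3 — inclusive area bounds and a
  strict circularity bound follow the wording of the published gate.

On synthetic images of non-overlapping ellipses with in-range areas and
low noise the chain recovers every planted nucleus exactly, and
measured areas land within a few percent of the analytic ellipse areas
(the test suite asserts ±10%).

## The 153-feature profile

Retained nuclei are pooled per sample and split into 10 evenly spaced
area bins of width 45 px² spanning [50, 500]; bins are half-open with
the last closed, so every in-range area has a bin. For each of six
parameters (area `Ar`, perimeter `Pe`, circularity `Ci`, aspect ratio
`AR`, solidity `So`, roundness `Ro`) the profile stores the mean and
the SD per bin and over all nuclei (2 × 6 × 11 = 132 features), plus
per-bin counts and percentages (20) and one spatial statistic (1):

* **SDs use the population convention** (divisor *n*): extreme bins
  often hold a single nucleus, whose spread is legitimately 0 rather
  than undefined. This is configurable in spirit — the SD of a
  single-observation bin is the only case where the two conventions
  disagree qualitatively.
* **Empty bins give missing means/SDs**, not zeros: a zero would
  fabricate a shape value. Missing values are excluded pairwise in all
  downstream statistics.
* **Compactness** is the Clark–Evans nearest-neighbour index: observed
  mean nearest-neighbour distance between nucleus centroids divided by
  its expectation $0.5\sqrt{A/n}$ under complete spatial randomness,
  count-weighted across a sample's images. The source analysis names a
  spatial-aggregation feature without printing a formula; the
  Clark–Evans index is the field's standard single-number choice and
  is documented here as this package's definition.

`normalize_profiles` log-transforms each feature and centres it on its
median (equivalently $\log(x/\tilde{x})$), giving every feature median
0. The transform is applied log-first because median-centering first
would create negative values on which the log is undefined;
non-positive raw values (possible for counts of 0) are flagged and set
missing. Feature values on this scale are approximately normal, which
`jarque_bera` can verify per feature.

## Feature and gene discovery

Class comparisons use the signal-to-noise ratio
$\mathrm{SNR} = (\mu_1 - \mu_2)/(\sigma_1 + \sigma_2)$ with class 1 the
chemosensitive group and sample SDs (divisor $n-1$): positive values
mark features higher in sensitive samples. Significance comes from
two-sided Welch *t*-tests (the unpaired, two-tailed choice that does
not assume equal variances), with Benjamini–Hochberg step-up control
(`bh_adjust`, cross-checked in the tests against both a hand-written
step-up oracle and `stats::p.adjust`).

* `select_morph_features` keeps features at FDR ≤ 2% and ranks them by
  SNR, mirroring the published screen that returned 15 features — 5
  with the highest and 10 with the smallest SNR.
* `select_genes` keeps genes passing both a geometric-mean fold-change
  cutoff (resistant/sensitive, computed as $2^{\Delta\text{mean}}$ on
  log2 data) and *t*-test *p* < 0.05.
* `tune_fold_change_cutoff` scores candidate cutoffs by training-set
  accuracy. Resubstitution is the default (matching how the original
  tuning curve was described); because resubstitution is flattered by
  overfitting and typically ties at small cutoffs, a `method = "loo"`
  flag re-selects and re-fits per held-out sample, which is where a
  peak above the noise fold-change scale actually emerges. Ties go to
  the smallest cutoff.

## The weighted-voting classifier

`wv_fit` is the package's core estimator and returns a classed
`"wv_model"` with `print`, `summary`, `coef` and `predict` methods.
Each selected gene $f$ votes $w_f (x_f - b_f)$, where $w_f$ is its
training SNR and $b_f$ the midpoint of its class means; the predictive
score of a sample is the average vote
$S = N^{-1}\sum_f w_f (x_f - b_f)$, and samples score above the cutoff
as sensitive. The $1/N$ normalization is ranking-equivalent to the
plain sum (a `normalize = FALSE` flag switches); the midpoint-vote
form is the classic weighted-voting formulation this family of
signatures is built on.

`roc_cutoff` sweeps all thresholds, computes the trapezoid AUC
(validated against concordant-pair counting and pROC), and calibrates
the operating cutoff by Youden's J, with ties resolved toward higher
sensitivity; a user-supplied cutoff (such as a published operating
point of −0.16) can be fixed instead. The bookkeeping identity linking
an operating point to overall accuracy,
$\mathrm{acc} = (\mathrm{se}\,n_+ + \mathrm{sp}\,n_-)/(n_+ + n_-)$, is
exposed as `operating_point_accuracy`; at sensitivity 95.2%,
specificity 70% and class sizes 165/67 it gives 87.9%.

`split_by_quantile` forms high/low score groups of size
`round(fraction * n)`; rounding (rather than ceiling) is what
reproduces a 171/73 partition of 244 samples at fraction 0.701.
`median_split` sends values equal to the median to the "high" group.

## Survival and integration

Kaplan–Meier curves, log-rank tests and Cox proportional-hazards fits
delegate to the survival package (`survfit`, `survdiff`, `coxph` with
Efron ties), with medians defined as the earliest time the survival
estimate reaches 0.5. The test suite re-derives the product-limit
estimator and the O−E log-rank table by hand on small instances to pin
the conventions. `supervised_gene_analysis` compares each gene between
the groups of a feature split (two-sided Welch, direction tagged
relative to the low group), and `feature_gene_correlation` screens all
feature–gene pairs by Pearson correlation at *p* < 0.005 with pairwise
deletion — deliberately without multiplicity correction, matching the
published screen; Pearson is appropriate because profile features are
approximately normal after normalization (Spearman is available behind
a flag).

## What the synthetic generators emulate

The generators' defaults are the study conditions:

* `simulate_nuclei_image`: 648 × 1072 px fields with ~400
  non-overlapping, anti-aliased dark ellipses of 50–500 px² on a noisy
  background (≈4000 nuclei per sample over ~10 fields). Ellipses give
  segmentation an analytic oracle; rejection sampling (10,000-attempt
  cap) enforces non-overlap because the measurement model assumes one
  component per nucleus. Elongation defaults to 1–2.5 and background
  noise SD to 0.02 on the unit intensity scale — values chosen once as
  visually typical of clean 20× H&E fields.
* `simulate_expression`: 232 samples with 67 resistant, log2-scale
  values, baseline means N(7, 1.5²); 2000 genes with 50 informative at
  log2 fold change 1 and noise SD 0.5 are desk-scale defaults (the
  real post-prescreen gene space was 14,084; nothing in the method
  depends on the ambient dimension).
* `simulate_feature_matrix`: profile-like matrices with a latent
  per-sample factor loading U(0.4, 1) on every feature plus N(0, 0.5²)
  noise. The latent factor reproduces the dominant-eigenvalue
  correlation structure that the package's own image→profile chain
  produces (about half the variance on one component) — binned
  features of the same nuclei are intrinsically correlated.
* `simulate_survival`: exponential event times (closed-form medians,
  exact proportional hazards) with the resistant hazard multiplied by
  the planted ratio; independent Uniform(0, u) censoring with u
  calibrated so the expected censored fraction matches the request.
  Defaults: sensitive median 25.8 months, hazard ratio 2.8, censoring
  0.3, echoing the printed progression-free survival structure of the
  cohort.

What they do **not** emulate: H&E colour and stain variation, touching
or overlapping nuclei, texture/chromatin features, platform effects and
batch structure in expression, non-proportional hazards, informative
censoring. Tests passing on these generators therefore validate the
computational contracts — segmentation accuracy on resolvable nuclei,
correct statistics, correct bookkeeping — not robustness to the messier
aspects of real slides and arrays.

## Numerical choices and degenerate inputs

* Constant images (or constant band-passed output) are a degenerate
  input for automatic thresholding and raise an error rather than
  guessing.
* Zero-spread genes carry no usable vote and are excluded from fits
  with a warning; a sample sharing no genes with a model is an error,
  while partially missing genes renormalize the vote with a warning.
* Constant score vectors give a degenerate ROC (AUC 0.5, cutoff
  flagged undefined).
* All-censored survival data yield a flat curve with undefined median;
  log-rank requires events and two non-empty groups; constant
  covariates are dropped from Cox fits with a warning.
* Every generator takes an explicit seed and restores the caller's RNG
  state, so identical arguments reproduce bit-identical artifacts and
  `run_pipeline` manifests hash identically across reruns.

## Known limitations

* The FDR ≤ 2% screen has an irreducible false-positive floor: with 15
  strong features among 153, a single null feature entering the
  selection requires only one of ~138 approximately uniform p-values
  below ≈ 0.002, which happens in roughly a quarter of independent
  cohorts (less under correlated features). Exact-set recovery of a
  planted signature is therefore a high-variance event across seeds,
  which is worth remembering when interpreting any single cohort's
  selected set.
* The perimeter estimator is unbiased for disks but mildly
  underestimates elongated boundaries (~3% at 2:1 elongation), so
  circularity near 1 is frequently capped — the same behaviour the
  original ImageJ-based workflow exhibits, via a different estimator.
* Resubstitution accuracy (the default tuning criterion) saturates and
  should not be read as generalization performance; use the LOO flag
  for an honest curve.

## Problem sizes used by the test and acceptance runs

The suite exercises: 20 images of 10–60 nuclei at 500 × 600 px for
segmentation recovery; 20 cohorts of 130 samples × 153 features for
planted-signature recovery; one 232-sample × 2000-gene cohort for
leave-one-out classification; 200 replicates of 60-sample null cohorts
for log-rank calibration; and 1000-sample cohorts for planted
hazard-ratio recovery. These sizes keep a full run in the low minutes
on a laptop while leaving Monte-Carlo margins comfortably inside the
asserted bands.
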