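# nucsig

Integrated analysis of tumor nuclear morphology and gene expression for
platinum chemotherapy response in serous ovarian carcinoma.

Advanced serous ovarian carcinoma is treated with platinum-based
chemotherapy, but patients who recur within six months of their last
platinum treatment (*chemoresistant*, versus *chemosensitive*) gain
little from it. `nucsig` implements, as a tested R pipeline, the two
linked analyses that address this stratification problem:

* **Tumor nuclear image profiles.** Nuclei are segmented from
  histology-style images (FFT band-pass filter, Otsu threshold,
  8-connected labelling), measured (area, perimeter, fitted-ellipse
  axes, convex hull), gated to 50–500 px² with circularity > 0.3, and
  summarized per patient as a 153-feature profile: for six parameters
  (area, perimeter, circularity, aspect ratio, solidity, roundness)
  the mean and SD in each of 10 evenly spaced area bins and overall
  (132 features), per-bin counts and percentages (20), and one spatial
  compactness statistic (Clark–Evans index).
* **A weighted-voting expression classifier.** Genes passing a
  fold-change and *t*-test screen each vote
  *w<sub>f</sub>*(*x<sub>f</sub>* − *b<sub>f</sub>*), with weight
  *w<sub>f</sub>* = SNR = (μ₁ − μ₂)/(σ₁ + σ₂) between the response
  classes and boundary *b<sub>f</sub>* the midpoint of the class
  means; the predictive score is the average vote
  *S* = *N*⁻¹ Σ *w<sub>f</sub>*(*x<sub>f</sub>* − *b<sub>f</sub>*),
  with the operating cutoff calibrated on an ROC curve (Youden's J, or
  a fixed published value). Feature discovery uses SNR ranking with
  Benjamini–Hochberg FDR control; high/low score or feature groups are
  compared by Kaplan–Meier, log-rank and covariate-adjusted Cox
  models, and morphology is linked to expression via supervised gene
  analysis and feature–gene Pearson correlation screens.

Synthetic-data generators (elliptical-nucleus images, two-class
expression matrices, exponential survival times — all with planted
ground truth) make every stage verifiable end to end without external
data. The package is aimed at computational pathology / genomics
researchers who want a reproducible, oracle-tested reference
implementation of this analysis family.

## Worked example

```r
library(nucsig)

## --- morphometry: image -> nuclei -> 153-feature profile -------------
sim <- simulate_nuclei_image(n_nuclei = 60, image_shape = c(400, 500),
                             area_range = c(80, 450), seed = 1)
nuclei <- extract_nuclei(sim$image)
nrow(nuclei)
#> [1] 60                      # every planted nucleus recovered
profile <- build_profile(nuclei, "patient_01", c(400, 500))
print(profile)
#> Nuclear image profile of sample 'patient_01' (153 features)
#>   nuclei: 60
#>   Mean_Ar_Total: 250.4  Compactness: 1.265

## --- expression: discovery -> weighted voting -> ROC ------------------
cohort <- simulate_expression(seed = 42)   # 232 samples, 67 resistant
genes <- select_genes(cohort$matrix, cohort$labels,
                      fold_change_cutoff = 1.5)
fit <- wv_fit(cohort$matrix, cohort$labels, genes)
print(fit)
#> Weighted-voting classifier
#>   genes: 50  | training samples: 232  (165 sensitive / 67 resistant)
#>   score cutoff: 0 (mean vote)
scores <- predict(fit, cohort$matrix)
roc_cutoff(scores, cohort$labels)
#> ROC: AUC = 1, cutoff = -0.3331 (sensitivity 1.000, specificity 1.000)

## --- survival stratification by score -------------------------------
clin <- simulate_clinical(cohort$labels, seed = 42)
grp <- split_by_quantile(scores, 0.701)
lr <- logrank_test(clin$pfs_months, clin$pfs_event, grp[clin$sample_id])
sprintf("log-rank chi-square %.2f, p = %.3g", lr$statistic, lr$p_value)
#> [1] "log-rank chi-square 32.61, p = 1.13e-08"
```

The planted cohort has 50 informative genes at a log2 fold change of 1,
so a perfect training AUC is expected; the score split separates the
planted survival difference (resistant hazard ratio 2.8) decisively.
`run_pipeline()` chains all stages — segmentation, profiles, feature
and gene discovery, model fitting, survival comparison, feature–gene
integration — into a run directory with per-artifact checksums in a
manifest; identical configuration and seed reproduce identical
artifacts.

See the vignette
(`vignettes/nuclear-morphometry-signatures.Rmd`) for the model
assumptions, parameter conventions (bin edges, SD conventions,
normalization order, tie rules) and the limits of what the synthetic
generators emulate.

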