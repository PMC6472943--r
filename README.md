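# tamsig

Derivation and scoring of tumor-associated macrophage (TAM) gene signatures
from bulk RNA-seq, with the companion analyses such signatures feed:
blood-monocyte cancer classification and survival analysis.

## The problem

TAMs are transcriptionally reprogrammed relative to the resident macrophages
of the same tissue, and circulating monocytes are systemically altered by the
presence of cancer. `tamsig` provides, for analysts working with such data:

- **Preprocessing** of count matrices: CPM filtering (CPM > 1 in at least N
  samples), TMM and upper-quartile normalization factors, log2-CPM, median
  centering, and empirical-Bayes batch adjustment.
- **Moderated differential expression**: per-gene variances shrunk toward a
  method-of-moments empirical-Bayes prior,
  `t = Δ / (s̃ √(1/n₁ + 1/n₂))` with `s̃² = (d₀s₀² + d s²)/(d₀ + d)`,
  BH-adjusted FDR, and the conventional `FDR ≤ 0.05`, `|log2FC| ≥ 1.5`
  selection gates.
- **The five-filter TAM signature cascade**: differential-expression gate
  (log2FC > 3, FDR < 0.05) → immune-compendium exclusion → co-expression
  gate (|r| ≥ 0.5 in a tumor cohort) → anchor-gene gate (r > 0.5, p ≤ 0.05
  versus a CD163-like pan-macrophage marker) → tumor-cell exclusion
  (cell-line median log2 expression > 6), plus the **signature score**: the
  per-sample median of median-centered signature-gene expression.
- **A liquid-biopsy classifier**: stratified 70/30 split, recursive feature
  elimination around a 500-tree random forest (`mtry = √p`, subset sizes
  2–30, 5×10-fold CV), one-shot test-set evaluation, Mann-Whitney ROC/AUC,
  and a permutation-null significance test with the add-one estimator
  `p = (1 + #{null ≥ observed}) / (1 + rounds)`.
- **Survival analysis**: Kaplan-Meier curves, Cox proportional hazards
  (`h(t|x) = h₀(t) e^{βx}`, Efron ties, Wald inference), exhaustive
  optimal-cutpoint dichotomization over all n−1 splits, two-gene summed
  scores, and univariate→multivariate covariate selection.
- **Cohort stratification**: CSF1-response High/Mid/Low k-means grouping and
  PAM50-style hierarchical subtype clustering (1 − Pearson distance, average
  linkage).
- **A synthetic-data module** that generates every input class above —
  negative-binomial two-class counts with planted fold changes, a tumor
  cohort whose survival hazard is proportional to a planted module score,
  a cell-line panel, and immune gene-set compendia — so the full pipeline
  runs and is tested without any external download.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` methods (KM curves,
ROC, RFE profiles, permutation nulls, cutpoint scans).

## Worked example

Run the signature arm end to end on synthetic data: simulate a 4 + 4
TAM-vs-RM count cohort with a 40-gene planted module (log2FC 4), preprocess,
test differential expression, derive the signature through all five gates,
score a 600-patient tumor cohort, and relate the score to survival:

```r
library(tamsig)

cfg <- sim_config(seed = 1, group_sizes = c(4, 4),
                  condition_labels = c("RM", "TAM"),
                  n_signal_genes = 40, effect_log2fc = 4)
b <- run_signature_pipeline(cfg)

b$signature
#> <tam_signature> 40 genes
#> # A tibble: 5 × 2
#>   stage             n_kept
#>   <chr>              <int>
#> 1 de_gate               40
#> 2 compendium_gate       40
#> 3 coexpression_gate     40
#> 4 anchor_gate           40
#> 5 cellline_gate         40

glance(b$scan)          # optimal-cutpoint scan of the signature score
#> # A tibble: 1 × 5
#>   optimal_cutoff    hr  p.value n_candidates n_significant
#>            <dbl> <dbl>    <dbl>        <int>         <int>
#> 1           1.23  4.02 7.00e-17          599           595

b$cox$score             # Cox fit on the standardized score
#> # A tibble: 1 × 8
#>   term     beta    hr conf.low conf.high     z  p.value flagged
#>   <chr>   <dbl> <dbl>    <dbl>     <dbl> <dbl>    <dbl> <lgl>
#> 1 score_z 0.702  2.02     1.76      2.32  10.0 1.47e-23 FALSE
```

Reading the output: all 40 planted module genes survive every gate and
nothing else does; the fitted hazard ratio per score standard deviation is
2.02 with CI (1.76, 2.32), recovering the simulated `cox_beta = ln 2`
(HR = 2); dichotomizing at the optimal cutpoint yields a high-vs-low hazard
ratio of 4.02 — larger than the per-SD effect, and with a selection-biased
p-value, both characteristic of min-p cutoff optimization (see the methods
vignette).

The classifier arm runs the same way:

```r
cls <- run_classifier_pipeline(rounds = 200)
glance(cls$rfe)         # optimal gene subset and CV metrics
cls$metrics             # held-out confusion-matrix metrics
cls$roc$auc             # Mann-Whitney AUC on the test set
glance(cls$permutation) # permutation-null accuracy and empirical p
autoplot(cls$permutation)
```

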