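---
title: "Methods: TAM signature derivation, monocyte classification, and survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAM signature derivation, monocyte classification, and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tamsig` re-implements, as a reusable and fully tested pipeline, the
computational core of a tumor-associated-macrophage (TAM) transcriptomics
workflow: RNA-seq count preprocessing, moderated differential expression, a
five-filter TAM gene-signature derivation with a median signature score, a
blood-monocyte cancer classifier built on recursive feature elimination (RFE)
around a random forest with a permutation-null significance test, survival
analysis with exhaustive optimal-cutpoint dichotomization, and CSF1/PAM50-style
cohort stratification. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data module does and
does not emulate.

## The scientific setting

Macrophages infiltrating tumors (TAMs) are transcriptionally reprogrammed
relative to tissue-resident macrophages (RMs), and circulating monocytes are
systemically altered by the presence of cancer ("tumor-educated" monocytes).
Three analysis arms follow from this:

1. **Signature arm.** Contrast TAM vs RM expression, distill the up-regulated
   genes into a compact TAM-specific signature by removing genes attributable
   to other immune lineages or to tumor cells themselves, and score bulk
   tumors by the median expression of the signature.
2. **Classifier arm.** Ask whether total blood monocytes carry enough signal
   to indicate the presence of cancer, using RFE with a random-forest learner
   and honest train/test separation, plus a permutation null to rule out
   overfitting artifacts.
3. **Survival arm.** Relate signature scores (or gene pairs such as
   SIGLEC1/CCL8) to disease-specific or recurrence-free survival via
   Kaplan-Meier curves and Cox proportional-hazards models, dichotomizing
   expression at the optimal cutpoint over all possible splits.

All public-cohort inputs (monocyte/TAM count matrices, a METABRIC-like tumor
cohort, a CCLE-like cell-line panel, immune gene-set compendia) are emulated
by the synthetic-data module, so every stage is testable offline.

## Preprocessing

- **CPM filter.** A gene is retained when its counts-per-million exceed
  `min_cpm` (default 1) in at least `min_samples` samples; `min_samples` is
  conventionally the size of the smallest condition group. The filter is
  monotone in both parameters.
- **Normalization.** Between-sample scaling factors by trimmed mean of
  M-values (TMM; 30% trim on log-ratios, 5% on abundances, inverse
  binomial-variance weights) or by the upper quartile of nonzero counts. Both
  are computed by `edgeR::calcNormFactors()` — the canonical implementation —
  behind the `normalization_factors()` surface, and rescaled to geometric
  mean 1. TMM is used for macrophage-style cohorts, upper-quartile for
  monocyte-style cohorts, mirroring the workflow the package encodes.
- **log-CPM.** `log2((count + prior) / (library x factor) * 1e6)` with a
  pseudo-count `prior = 0.5` (the conventional default; configurable). The
  transform is strictly increasing in the count and scale-invariant up to the
  pseudo-count.
- **Batch adjustment.** Parametric empirical-Bayes location/scale correction
  per gene and batch, with no covariate model matrix, delegated to
  `sva::ComBat(mod = NULL)`. Per-gene batch differences collapse to sampling
  noise; the grand mean is restored. Batches of one sample are an error.
- **Median centering** subtracts each gene's across-sample median
  (idempotent); it is the scale on which signature scores are defined.

## Moderated differential expression

`fit_moderated_t()` implements the empirical-Bayes moderated t for a
two-group contrast. Per gene the pooled residual variance \(s_g^2\) (with
\(d = n_1 + n_2 - 2\) df) is shrunk toward a prior \(s_0^2\) with \(d_0\)
prior df:

\[ \tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
   t_g = \frac{\Delta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}, \]

with \(\Delta_g\) the difference of group means on the log2 scale and p-values
from a t distribution on \(d_0 + d\) df. The prior is estimated by the
closed-form method of moments on \(\log s_g^2\) (matching the standard
empirical-Bayes estimator; the test suite verifies agreement with `limma` to
machine precision on heterogeneous-variance data). Numerical choices:

- `d0 = 0` reproduces the ordinary pooled t exactly; an infinite estimate is
  capped at `10 * d`, a finite stand-in for full shrinkage.
- Genes with zero residual variance are excluded from prior estimation but
  still shrunk, so every statistic is finite.
- DEG selection gates: BH-adjusted FDR \(\le\) 0.05 and log2 fold change
  \(\ge 1.5\) (up) or \(\le -1.5\) (down), both configurable. This package
  deliberately omits voom-style precision weights; consequently absolute DEG
  counts from weighted analyses are not comparable, and planted-effect
  recovery (power \(\ge 0.8\) at the 40 + 40 / fold-change-4x / dispersion-0.1
  design point) is the tested property instead.

## The five-filter signature cascade

`derive_tam_signature()` applies, in order, with the inequalities exactly as
stated in each gate:

1. **DE gate** — keep genes with `log2fc > 3` and `fdr < 0.05` in the
   TAM-vs-RM contrast.
2. **Compendium gate** — remove genes belonging to any immune cell-type set
   not whitelisted as macrophage/monocyte lineage.
3. **Co-expression gate** — on the tumor cohort, keep genes with absolute
   Pearson correlation \(\ge 0.5\) with at least one other surviving
   candidate. The procedure described in the source workflow invokes a
   redundancy-*removal* routine while its prose describes a co-expression
   *selection*; selection is the default here (it matches the stated
   sentence), and redundancy removal (`caret::findCorrelation`) is available
   via `coexpr_mode = "reduce"`.
4. **Anchor gate** — keep genes positively correlated (`r > 0.5`,
   `p <= 0.05`, t transform on \(n-2\) df, no multiplicity correction) with
   a designated pan-macrophage anchor gene (CD163 in the original setting).
5. **Tumor-cell exclusion gate** — remove genes whose median expression
   across a tumor cell-line panel exceeds log2 6; genes absent from the
   panel are kept, as there is no evidence they are tumor-cell expressed.

The cascade is deterministic, its per-stage survivor counts are
non-increasing, and disabling any single gate provably yields a superset of
the enabled result (tested). The **signature score** of a sample is the
median of the median-centered expression of the signature genes.

## The monocyte classifier

- **Split.** 70/30 stratified by class with per-class *ceiling* rounding —
  the only rule consistent with partitioning 45 + 32 samples into
  (32 + 23) train / (13 + 9) test.
- **RFE.** Within each of 5 x 10 stratified CV resamples: fit a 500-tree
  forest on all features, rank by impurity (Gini) importance (permutation
  importance behind a flag; ties broken lexicographically by gene id for
  determinism), refit on each subset size of the 2..30 grid, and record
  held-out accuracy/sensitivity/specificity. The optimal size maximizes mean
  CV accuracy (ties toward the smaller subset); the final model is refit on
  the full training set restricted to the top-ranked genes of the
  full-training-set ranking. `mtry` is recomputed as \(\lfloor\sqrt p\rfloor\)
  at every fit. The test set is touched exactly once, after selection is
  frozen.
- **Evaluation.** Confusion matrix with cancer as the positive class;
  accuracy/sensitivity/specificity with zero-denominator cases reported as
  undefined (`NA`), never 0. ROC/AUC by the Mann-Whitney rank formulation
  (ties count one half).
- **Permutation null.** Each round permutes the class labels and records the
  mean repeated-CV accuracy of a forest on the fixed optimal gene set; the
  empirical p uses the add-one estimator
  \(p = (1 + \#\{ \text{null} \ge \text{observed}\})/(1 + R)\), whose floor
  at 1,000 rounds is 0.001.

## Survival analysis

- **Kaplan-Meier** curves via the product-limit estimator
  (`survival::survfit`).
- **Cox models** via `survival::coxph` with Efron tie handling (Breslow
  behind a flag); hazard ratios with normal-approximation 95% CIs and Wald
  p-values; listwise exclusion of missing covariates; monotone likelihoods
  (perfect separation) flagged rather than silently returned. Clinical
  covariates use the conventional codings: ER/PR/Her2 as +/− indicators,
  grade ordinal I–III, age dichotomized at 55 years, tumor size at 50 mm.
- **Optimal-cutpoint scan.** Every one of the \(n-1\) midpoints between
  consecutive distinct score values is evaluated by dichotomizing and
  fitting a univariate Cox model; the optimal cutoff minimizes the p-value
  subject to a minimum arm size (`min_group`, default 1 = every possible
  cutoff; a guard rail is configurable because tiny arms are numerically
  fragile). Ties on p are broken toward the more balanced split.
  **Numerical choice:** candidates are ranked by the likelihood-ratio p by
  default. The Wald p degenerates toward 1 whenever a split separates
  survival perfectly (monotone partial likelihood), which would corrupt
  min-p ranking precisely at the strongest splits; the LR statistic has a
  finite supremum and remains well behaved. Score (log-rank) and Wald
  rankings are available via `p_method`. Single-covariate model reporting
  elsewhere stays Wald-based.
  The scan's minimum p is *not* a valid single-test p-value: under the null
  it falls below 0.05 in far more than 5% of datasets (the test suite
  documents ~40–50% at n = 30), a known optimism of min-p selection.
- **Two-gene score.** For a gene pair the combined score is the sum of
  per-gene z-scores (median-centered and raw sums behind `normalize`); since
  dichotomization depends only on score order, any monotone per-gene
  normalization that preserves the ordering gives identical scans.
- **Univariate → multivariate selection.** Covariates with univariate Wald
  p below 0.05 enter a single joint fit. Note Cox non-collapsibility:
  univariate hazard ratios attenuate when independent prognostic covariates
  are omitted, so joint estimates near the data-generating value, not near
  the marginal ones, are the tested property.

## Cohort stratification

- **CSF1 High/Mid/Low**: k-means (k = 3, 25 restarts, best within-cluster
  sum of squares kept; the initialization count is a package default, as the
  procedure it encodes names no value) on the sample-by-CSF1-signature-gene
  submatrix; clusters are relabeled High/Mid/Low by descending mean
  signature expression, so the labels never depend on RNG or cluster
  indexing. With exactly three samples each sample is its own group.
- **PAM50-style subtypes**: agglomerative clustering of samples with
  distance 1 − Pearson correlation and average linkage, cut at a fixed
  k = 5 (the source procedure states no cut rule; five intrinsic subtypes is
  the natural choice and `k` is exposed). Correlation distance makes the
  assignment invariant to per-sample positive affine transforms.
  Cluster-to-subtype naming must be supplied by the caller; the package
  never invents biological labels.

## The synthetic-data module

Generators are pure functions of `(config, seed)`; identical inputs give
bitwise-identical outputs.

- **Two-class counts** (`simulate_two_class_counts`): negative-binomial
  counts (the standard bulk RNA-seq noise model) with gene-wise baseline
  abundances spanning ~8 log2 units, a shared dispersion (default 0.1,
  typical for bulk human data; gene-wise dispersion is a config extension,
  not the default), library sizes uniform on 8–12 million, and exactly
  `n_signal_genes` genes shifted by `effect_log2fc` in the second class.
  Optional two-batch structure adds a log-scale location offset.
- **Tumor cohort** (`simulate_tumor_cohort`): signature genes (plus the
  anchor) load on a single latent factor with loading \(\sqrt{1.5}\), giving
  expected pairwise correlation ≈ 0.6 — deliberately above the 0.5
  co-expression gate so the planted module clears it with margin. Survival
  is exponential with hazard \(h_0 e^{\beta z}\), \(z\) the standardized
  realized signature score, \(h_0 = 0.005\)/month and \(\beta = \ln 2\) by
  default; censoring is independent uniform over a window solved so the
  expected null censoring fraction equals `censor_rate` (default 0.6, giving
  ≈40% events). Clinical covariates are drawn with declared marginals
  (ER+ 75%, PR+ 60%, Her2+ 15%, grade 20/45/35%, age ~ N(61, 12), size
  log-normal around 22 mm) and are independent of survival by design.
- **Cell-line panel** and **reference sets** provide the tumor-cell
  exclusion input (expressed genes centered at log2 9, others at 2, so the
  median-6 gate separates them essentially surely) and a 17-set immune
  compendium (30 genes each, one macrophage-lineage set), a 112-gene
  CSF1-response-like set, a 50-gene PAM50-like set, and a designated anchor
  gene outside the planted module.
- **Gaussian feature matrix** (`simulate_feature_matrix`): unit-variance
  features with a stated pooled-SD class shift, for classifier design points
  where the effect size should be specified directly.

What the generators do **not** emulate: realistic breast-cancer covariance
beyond one planted module, subtype-specific expression programs, gene-wise
dispersion trends, batch-by-condition confounding, or informative censoring.
Passing tests therefore demonstrate that the algorithms recover planted
structure under their stated assumptions — not that any particular biological
conclusion transfers to real cohorts.

## Problem sizes used by the test suite

The suite exercises each operating point once at a fixed seed: DE power at
40 + 40 samples x 2,000 genes; Cox CI coverage over 40 simulated cohorts of
n = 600; RFE recovery at 200 features / n = 60; the permutation-null
distribution at 55 samples x 17 features with 60 rounds (the acceptance
script runs 200); null properties over 6–40 seeds each. These sizes were
chosen to estimate each property with comfortable margin while keeping a
full run of the suite to a few minutes.

## Known limitations

- No voom-style precision or sample-quality weights; heteroskedastic
  libraries are handled only through normalization.
- Two-group contrasts only; no multi-factor designs.
- The RFE search refits forests exhaustively over the subset-size grid;
  for feature universes far beyond ~10^3 a pre-filter is advisable.
- The optimal-cutpoint p-values are selection-biased by construction
  (documented above); they are reported as the procedure defines them, not
  corrected.
- Batch adjustment assumes no batch-condition confounding; it fits no
  covariates.
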