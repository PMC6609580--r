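---
title: "Methods: pan-cancer DNA-methylation aging acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer DNA-methylation aging acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`agingaccel` implements a pan-cancer aging-acceleration analysis over paired
tumor / adjacent-normal multi-omics profiles. The pipeline has six analysis
stages, each usable on its own:

1. **Preprocessing** — per-tissue standardization of DNA methylation
   (z-score by adjacent-normal statistics, removal of the top three
   normal-derived principal directions, a final z-score), median
   normalization of expression, binarization of mutation counts.
2. **Aging clock** — a Kruskal-Wallis screen for age-associated CpGs
   (p < 0.05, Benjamini-Hochberg FDR < 0.2 against the binary age label,
   old = age > 60 y), then a linear ε-insensitive support-vector regressor
   trained on binary age labels with leave-one-tissue-out cross-validation
   over a swept marker count. A sample's *aging score* is the regressor
   output; scores above 0.5 label a sample "old". *Aging acceleration* of
   a tumor/normal pair is the tumor score minus the paired normal score.
3. **Acceleration-associated modules** — per cancer, LASSO
   (`alpha = 1`, 5-fold CV, minimal-MSE model, sparsest on ties) of the
   acceleration vector on (a) the binary mutation matrix and (b) the paired
   expression-difference matrix; the two selected sets are linked into a
   bipartite network by per-pair Kruskal-Wallis tests (p < 0.05,
   FDR < 0.2).
4. **eQTL modules** — for each selected mutation: differential-expression
   candidates (paired sign test p < 0.05, FDR < 0.2, fold change > 2),
   Kruskal-Wallis ranking against mutation status, ternary discretization
   (mean ± sd/2), greedy mRMR re-ranking (mutual information in bits), and
   leave-one-out module sizing at the smallest size attaining the minimal
   error.
5. **Enrichment** — exact hypergeometric upper-tail tests of module genes
   against GMT gene sets with BH adjustment, and Pearson correlation of
   per-cancer `(1 − FDR)` profiles.
6. **Cross-cancer network** — pairs are *accelerated* when acceleration
   is strictly positive; for each cancer pair, two-sample
   Kolmogorov-Smirnov statistics are accumulated over all cross-cancer
   module-gene pairs separately in the accelerated and non-accelerated
   groups, and the similarity is `sum |KS_acc − KS_non| / (ln N1 + ln N2)`.
   Edges are chosen top-k (default 10) or by strict threshold (default
   100).

# The synthetic world

The simulator (`generate_cohort()`) is a first-class module: every
downstream stage is tested against cohorts with known ground truth, so the
package requires no external data. It emulates:

- **Tissues and pairs.** `n_tissues` pseudo-tissues, each with
  `samples_per_tissue` patients contributing one tumor and one matched
  normal sample. Ages are uniform on `[30, 85]` so both age classes are
  populated in every tissue.
- **Aging CpGs.** A minority of CpGs (default 20 of 2000) shift by
  `aging_effect` (default 0.3 beta units) between old and young samples, in
  a random but CpG-consistent direction. Baselines are uniform on
  `[0.2, 0.8]` (narrowed to `[0.3, 0.7]` for aging CpGs so planted shifts
  rarely clip at the `[0, 1]` boundary); Gaussian noise (sd 0.05) is
  clipped to the beta range.
- **Technical factors.** Three latent factors with per-CpG loadings
  (sd 0.02) and per-sample standard-normal scores. These are the variation
  the SVD step exists to remove: without them the planted age signal is
  itself the leading principal component of a tissue's normals and
  detrending would strip it — with them, the top three components are
  technical and the age signal survives, exercising the intended causal
  path of the normalization.
- **Tumor acceleration.** Each pair's injected acceleration is
  `N(tumor_accel_effect, accel_sd)` plus `driver_accel_effect` per carried
  driver mutation (defaults 0.3, 0.25 and 0.3, in score units). It is
  realized by shifting the planted aging CpGs of the tumor sample in the
  age direction by `acceleration × aging_effect` beta units, so elevated
  scores *emerge through the clock* rather than being injected post hoc.
  The spread keeps a minority (~12%) of pairs non-accelerated, which the
  cross-cancer network stage requires; the per-pair values are recorded in
  the ground truth.
- **Drivers and modules.** Drivers are Bernoulli(0.3) per tumor;
  background mutations Bernoulli(0.05); normals carry no somatic
  mutations. Each driver perturbs a disjoint gene module: module genes are
  upregulated by `module_effect` (log2, default 2) in *all* tumors, plus a
  further `module_effect` in driver carriers. The constitutive part makes
  module genes pass the paired DEG filter (fold change > 2); the
  carrier-dependent part carries the mutation association the eQTL stage
  detects. A carrier-only shift cannot satisfy both at a 0.3 carrier rate
  (the median pair would be unshifted).
- **Expression noise** is log2-normal with sd 1.0. This value is
  deliberate: it puts single planted genes in the
  informative-but-insufficient regime (one gene classifies carrier status
  imperfectly, several genes together classify it well), which is the
  regime a module-*sizing* procedure is designed for, and it is typical
  log-scale biological variability.

What a green test does **not** establish: the simulator has no CpG island
structure, no copy number, no mutation signatures, no realistic age
distribution, and independent noise within channels. Recovery results
certify the pipeline's statistical machinery on its stated world, not
performance on real cohorts.

# Numerical and design choices

- **Regressor.** No SVM library is assumed; the linear ε-insensitive SVR
  (C = 1, ε = 0.1) and hinge-loss SVC (C = 1) are exact dual
  coordinate-descent solvers (compiled), deterministic under cyclic sweeps.
  Features are standardized inside each fold; the bias is an augmented,
  mildly regularized column.
- **Marker-count selection.** The screen orders candidates by ascending
  p (ties by CpG id); the sweep grid is `1..min(50, #candidates)`; fold
  errors are unweighted means over tissues; the smallest count attaining
  the minimum is chosen. A score of exactly 0.5 labels a sample young.
- **LASSO selection.** Among lambdas whose CV MSE ties the minimum
  (within 1e-10) the largest lambda — the sparsest model — is chosen. Fold
  assignment derives from a stored seed. Mutations observed in fewer than
  3 tumors are excluded from the design matrix.
- **mRMR.** Mutual information in bits; the incremental greedy form
  (relevance minus *mean* MI against already-selected genes); ties broken
  by gene id, making the ranking deterministic.
- **LOOCV sizing on discretized features.** The sizing classifier sees the
  ternary-discretized expression differences (the workflow order puts
  discretization before the module search); the continuous variant is
  available via `find_modules(loocv_features = "continuous")`. With
  continuous features and a strong planted effect, one gene is individually
  sufficient and the smallest-on-ties rule collapses every module to size
  1-2; discretization caps per-gene information, which is what lets
  multi-gene modules emerge. A module whose best LOOCV error is ≥ 0.4 is
  flagged non-informative. Note the error is the plain misclassification
  fraction, so for very imbalanced mutations the flag is conservative.
- **Median normalization** scales each sample to the grand median of the
  pre-scaling sample medians (midpoint convention for even counts).
  Zero-variance features are dropped, not imputed, at z-score steps.
  Sample standard deviations use the n−1 denominator throughout.
- **SVD detrending** removes projections of *both* tumor and normal
  samples onto the normal-derived directions (the normal basis is the
  batch estimate; tumors share the technical factors).
- **Enrichment universe** defaults to the union of genes across the
  collection; tails are computed by log-space summation of exact terms.
- **Similarity normalizer.** The denominator is `ln(N1) + ln(N2)` (the
  formula), not the number of gene pairs (the prose); expression entering
  the K-S statistics is the median-normalized tumor expression of module
  genes, continuous. Accumulated sums are computed over sorted values so
  the similarity is *exactly* symmetric under swapping the two cancers.
  Gene pairing is all-vs-all between the two modules.
- **Determinism.** All randomness flows from one root seed, expanded per
  stage; a rerun of `run_pipeline()` with the same configuration
  reproduces every output bitwise (manifest wall times excepted).

# Known limitations

- The clock predicts the binary age group, not calendar age; it is not a
  Horvath-style elastic-net clock.
- Cross-cancer similarity has no significance model; edges are descriptive.
- The bipartite and eQTL stages condition on LASSO selections; their error
  rates are not corrected for that selection step.
- With very few non-accelerated pairs in a cancer, that cancer is excluded
  from the similarity network (a guard, not an error).
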