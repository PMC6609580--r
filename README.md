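# agingaccel

Pan-cancer aging-acceleration analysis from paired tumor / adjacent-normal
multi-omics profiles (DNA methylation, expression, somatic mutations).

Cancers age faster than the tissue they arise in: DNA-methylation (DNAm)
profiles carry an epigenetic age signal, and the gap between a tumor's DNAm
"aging score" and its matched normal's score — the **aging acceleration** —
can be mined for the mutations and expression programs that travel with it.
`agingaccel` packages that analysis as a tested pipeline:

1. **Aging clock.** Age-associated CpGs are screened per CpG with the
   Kruskal-Wallis test against the binary age label (old = age > 60 y;
   retain p < 0.05 and Benjamini-Hochberg FDR < 0.2), then a linear
   ε-insensitive support-vector regressor is trained on the binary labels
   with leave-one-tissue-out cross-validation over a swept marker count.
   A sample is "old" when its score exceeds 0.5; acceleration of a pair is
   `score(tumor) − score(normal)`.
2. **Acceleration-associated modules.** Per cancer, LASSO (α = 1, 5-fold
   CV, minimal-MSE model) of the acceleration vector on the binary mutation
   matrix and on the paired expression-difference matrix; the selected sets
   are linked into a mutation-expression bipartite network by
   Kruskal-Wallis tests.
3. **eQTL modules.** Per selected mutation: paired sign-test DEG filter
   (p < 0.05, FDR < 0.2, fold change > 2), Kruskal-Wallis ranking, ternary
   discretization (mean ± sd/2), greedy mRMR re-ranking
   (`max_g R(g) − D(g)` over mutual information), and LOOCV module sizing
   at the smallest size with minimal error.
4. **Enrichment.** Exact hypergeometric upper tail
   `P(X ≥ k)` of module genes against GMT gene sets, BH adjustment, and
   cross-cancer Pearson correlation of `(1 − FDR)` profiles.
5. **Cross-cancer network.** For each cancer pair, two-sample
   Kolmogorov-Smirnov statistics `KS = sup|F1 − F2|` accumulated over all
   cross-cancer module-gene pairs, separately in aging-accelerated
   (acceleration > 0) and non-accelerated samples:
   `similarity = Σ|KS_acc − KS_non| / (ln N1 + ln N2)`; edges by top-k or
   strict threshold.

A synthetic paired-cohort generator with known ground truth (planted aging
CpGs, driver mutations, perturbed expression modules, technical factors)
makes the whole pipeline testable offline. See the methods vignette
(`vignettes/aging-acceleration-methods.Rmd`) for the model, parameter
defaults and their rationale, and limitations.

## Worked example

```r
library(agingaccel)

g    <- generate_cohort(synthetic_config(seed = 1))  # 11 tissues x 30 pairs
norm <- preprocess_cohort(g$cohort)                  # z-score / SVD(3) / z-score

anno <- norm$annotations
ni   <- anno$status == "normal"
cands <- screen_markers(norm$dnam[anno$sample_id[ni], ],
                        age_label(anno$age[ni]))
nrow(cands)
#> [1] 27
sum(g$truth$aging_cpg_ids %in% cands$cpg_id)         # all 20 planted CpGs found
#> [1] 20

model <- train_clock(norm$dnam[anno$sample_id[ni], ],
                     age_label(anno$age[ni]), anno$tissue[ni], cands$cpg_id)
model
#> DNAm aging clock: 4 markers, CV error 0.01627

sc <- score_samples(model, norm$dnam, anno)
at <- acceleration_test(sc$pairs$tumor_score, sc$pairs$normal_score)
sprintf("K-W p = %.3g; median gap = %.3f; mean gap = %.3f",
        at$p, at$median_diff, at$mean_diff)
#> [1] "K-W p = 4.99e-32; median gap = 0.719; mean gap = 0.588"
```

The screen returns 27 candidates — the 20 planted aging CpGs plus a few
false positives; leave-one-tissue-out cross-validation settles on a 4-marker
clock with a held-out balanced error of 1.6%, and tumor scores show the
planted aging acceleration (Kruskal-Wallis p ≈ 5e-32; tumors score a median
0.72 higher than their paired normals).

The full pipeline (simulate → preprocess → clock → modules → eqtl →
enrichment → network, with a JSON manifest and TSV outputs):

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

or from the shell: `Rscript inst/cli/pipeline.R run --out run1 --seed 1`.

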