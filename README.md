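# lungsig

Transcriptomic signature discovery for separating two clinically similar
diseases. The motivating problem is distinguishing chronic obstructive
pulmonary disease (COPD) from interstitial lung disease (ILD) on lung
gene-expression profiles: the two conditions share clinical traits yet need
different treatment, so a compact expression biomarker that classifies a
patient as COPD (positive class) or ILD (negative class) has direct
diagnostic value. The package implements the full discovery pipeline on any
two-class genes × samples expression matrix and ships a synthetic-data
generator with planted ground truth, so every stage is testable without
access to patient data.

## Method

1. **Cross-platform harmonization** — two matrices (e.g. two microarray
   platforms) are restricted to their common genes and quantile normalized
   (every sample receives the same empirical value distribution; ties share
   the mean of the rank means they span).
2. **mRMR ranking** — expression is discretized per gene into three states
   (z-score against ±`k_sd`, default 1). Relevance of gene *g* for label *t*
   is the mutual information *I(g, t)*; redundancy against the already
   selected set Ω_s is R(g) = (1/m) Σ_{gᵢ∈Ω_s} I(g, gᵢ). Greedy forward
   selection maximizes *I(g, t)* − R(g) (MID, default) or *I(g, t)* / R(g)
   (MIQ) at each step, producing a ranked list that favours genes that are
   informative about the disease *and* non-redundant with each other.
3. **Incremental feature selection (IFS)** — for every k, a support vector
   machine (RBF kernel, cost 1, gamma = 1/k, per-fold feature scaling — the
   classic libsvm defaults, implemented internally via SMO) is evaluated on
   the top-k genes by leave-one-out cross-validation (LOOCV), giving an
   accuracy-vs-k curve.
4. **Signature choice** — the smallest k on the plateau of the IFS curve:
   accuracy strictly within `delta` (default 0.01) of the curve maximum and
   at least `acc_floor` (default 0.90).
5. **Final evaluation** — the classifier is refitted on all training samples
   and scored on the independent test set; accuracy, sensitivity
   (TP/(TP+FN), positive = COPD) and specificity (TN/(TN+FP)) are reported,
   plus a hierarchical-clustering heatmap of all samples on the signature.

## Worked example

```r
library(lungsig)

g   <- generate_dataset_pair(synthetic_spec(seed = 42))   # 5 informative x3 + 200 noise genes, 60+60 samples
res <- run_pipeline(g$pair, top_n = 20, k_max = 20)

head(res$ranked, 5)
#>  rank    gene_id     score
#>     1     sig002 0.4271799
#>     2     sig004 0.2437651
#>     3     sig001 0.2306559
#>     4 sig005_r02 0.2180130
#>     5 sig003_r01 0.2054818

res$selection
#> $chosen_k:  2        # smallest k on the accuracy plateau
#> $argmax_k:  3        # where the IFS curve peaks
#> $accuracy:  0.992    # train LOOCV accuracy at chosen_k

res$test$cm; round(res$test$metrics, 3)
#>               Actual POS Actual NEG
#> Predicted POS         59          2
#> Predicted NEG          1         58
#>   acc    sn    sp
#> 0.975 0.983 0.967

cluster_heatmap(g$pair, head(res$ranked$gene_id, 10))
#> clustering_result: 240 samples, 10 genes (correlation distance, average linkage)
#>   2-cut purity 1.000
```

The ranking puts planted signal genes (`sig...`, including their correlated
redundant copies `_r..`) ahead of all 200 noise genes; two genes already
classify the held-out test samples at 0.975 accuracy, and clustering the
combined 240 samples on the top ten genes separates the classes perfectly
(purity 1.0 against the true labels).

A command-line interface wrapping the same steps
(`simulate`, `rank`, `ifs`, `evaluate`, `report`) is installed at
`system.file("cli", "lungsig.R", package = "lungsig")`.

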