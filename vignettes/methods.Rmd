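---
title: "Methods: mRMR/IFS signature discovery for two-class expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mRMR/IFS signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lungsig discovers a compact gene signature that separates two clinically
similar diseases — the motivating case is COPD (positive class) versus ILD
(negative class) on lung expression profiles — and quantifies how well a
support-vector classifier built on that signature generalizes to an
independent test cohort. This vignette records the statistical model behind
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices made where the
design was genuinely open.

## Data model and harmonization

The core container is a genes × samples real matrix with unique identifiers
and a binary label per sample (`expression_matrix`). The two-cohort design —
training samples measured on one platform, test samples on another — is
modelled by `dataset_pair`: same genes in the same order, disjoint samples.

`intersect_genes` restricts both matrices to their common genes and fixes a
single lexicographic row order, so results cannot depend on the incidental
gene order of the input files. `quantile_normalize` forces every sample to
share one empirical distribution: the value at within-sample rank *r* becomes
the mean of the rank-*r* order statistics across samples. Two open points were
settled as follows:

* **Joint vs separate normalization.** Each dataset is normalized separately
  (the `run_pipeline` default): the test cohort must be usable without access
  to the training cohort. Nothing prevents normalizing a combined matrix
  first if both are available.
* **Ties.** Tied values within a sample receive the mean of the rank means
  their tie block spans ("ties = average"). This is deterministic and
  symmetric in the tied entries; note that a tied column is then *not* a
  permutation of an untied column's values (the tie block collapses several
  rank means into their average). The transform is idempotent either way.
* **Missing values.** Gene rows containing any missing or non-numeric entry
  are dropped at load time (with a count), because the downstream
  discretization and mutual-information machinery assume complete rows.

## mRMR ranking

Continuous expression is reduced to three states per gene: values are
z-scored across samples and mapped to −1/0/+1 with a threshold of `k_sd`
standard deviations (default 1.0, the historical default of the classical C
implementation of mRMR). The threshold is inclusive (|z| ≥ k_sd maps to the
extreme states); on continuous data the boundary has measure zero, but the
inclusive rule also gives the intuitive answer on symmetric integer fixtures.
A zero-variance gene maps to the all-zero state and can never look
informative.

With states in hand, relevance of gene *g* for the label *t* is the plug-in
mutual information *I(g, t)* and redundancy against the selected set
Ω<sub>s</sub> of size *m* is R(g) = (1/m) Σ<sub>gᵢ∈Ω_s</sub> I(g, gᵢ).
`mrmr_rank` greedily selects argmax I(g, t) first and then repeatedly
maximizes either I(g, t) − R(g) (**MID**, the default — the difference form
is the one printed in the classical formulation) or I(g, t)/R(g) (**MIQ**).
Numerical conventions:

* logarithms base 2 (bits); the base rescales scores but can never reorder
  (asserted by test against a nats-based oracle);
* ties in the objective (within 1e−12) break toward the lexicographically
  smallest gene id, making the ranking deterministic and independent of input
  row order;
* under MIQ, step 1 is pure relevance, and a later zero redundancy is
  replaced by machine epsilon so the objective stays total;
* a fully constant matrix therefore ranks genes lexicographically with all
  scores zero.

The greedy path is verified against a brute-force oracle (recomputing the
full objective over all remaining candidates at every step, with mutual
information computed through entropies) on randomized fixtures.

## IFS, LOOCV and the SVM

For k = 1..k_max the top-k ranked genes are scored by leave-one-out
cross-validation: N rounds, each holding out one sample and training on the
other N−1. The classifier is a C-support-vector machine with RBF kernel,
encoded by `classifier_spec`. "Default parameters" of the classical R/libsvm
implementation are made explicit: cost = 1, gamma = 1/n_features, and
feature scaling to zero mean/unit variance. Because no SVM library is
assumed at run time, the package carries its own SMO solver (C++,
maximal-violating-pair working-set selection, stopping tolerance 1e−3 on the
KKT violation, intercept from the violating-pair bounds). On shared fixtures
it agrees with scikit-learn's SVC to within the stopping tolerance.

Two leakage/determinism decisions matter:

* scaling parameters are refitted inside every fold on the N−1 training
  samples only, so the held-out sample never influences its own
  preprocessing (the original study does not say whether it did this; it can
  shift accuracies by a few samples, which is one reason real-data accuracy
  is not an exact reproduction target);
* samples are processed in sorted sample-id order and the solver has no
  random component, so repeated runs and column-permuted inputs give
  bitwise-identical confusion matrices. Decision values of exactly zero
  predict the positive class.

`select_signature_size` formalizes the usual visual plateau judgment. Among
sizes whose accuracy is strictly above (curve maximum − delta) and at least
`acc_floor`, the smallest k wins; the global argmax is reported alongside.
Defaults delta = 0.01, acc_floor = 0.90. The strict inequality reproduces the
intended hand rule (a point exactly delta below the maximum is *not* on the
plateau); with delta = 0 the qualifying set degenerates to the argmax set. If
no size reaches the floor, the argmax is returned with a warning flag.

## Synthetic data: what it emulates, what it does not

`synthetic_spec`/`generate_dataset_pair` produce a stylized two-class world
with exactly the structure the ranking stage exploits:

* **informative genes** — class-conditional Gaussians, mean shift
  `effect_size` (in within-class SD units; default 3, a strong,
  unambiguously recoverable signal) with the shift direction alternating
  across blocks. The alternation mirrors real signatures, which mix up- and
  down-regulated genes; it also matters technically, because an
  all-one-direction signal lives entirely in each sample's profile mean,
  which Pearson-correlation distance removes — clustering would be blind to
  an effect the classifier sees easily;
* **redundant copies** — each informative gene carries
  `n_redundant_per_informative` copies, `copy = rho * parent +
  sqrt(1 - rho^2) * noise`, so the within-class correlation with the parent
  is exactly `rho` (default 0.7, typical of tightly co-expressed modules)
  and the within-class variance stays 1. The pooled (label-ignoring)
  correlation is higher because both share the class shift;
* **noise genes** — label-independent N(0, `noise_sd`);
* two independent draws form train and test (same population, different
  cohort), optionally with a per-gene log-normal scale jitter on the test
  draw to mimic a second platform.

Defaults (60+60 samples, 5 informative × (1+2) + 200 noise) are the regime
the property-based test suite states. The generator does **not** emulate
microarray physics (background, saturation), probe-level effects, batch
structure beyond the scale jitter, heavy-tailed or log-normal intensities,
or covariates. A green test on this world therefore establishes algorithmic
correctness (ranking recovers planted relevance/redundancy structure, the
classifier generalizes across independent draws, null data yields chance
accuracy) — it does not certify performance on any real cohort.

One property deserves a note: with redundant copies at rho = 0.7 and only a
slightly attenuated shift, a copy is statistically close to interchangeable
with its parent at n = 120, so the recovery guarantee is stated on the
combined window of the top (n_informative + n_redundant) ranks; without
copies, all informative genes are expected inside the top
n_informative + 5 ranks directly. Both forms are asserted in the acceptance
suite at 95% over 50 seeded replicates.

## Reporting

`cluster_heatmap` combines train and test samples, restricts to the
signature, z-scores each gene for display only (stored matrices are never
modified), and clusters samples and genes agglomeratively — defaults
correlation distance and average linkage, the common choice for expression
heatmaps; both are recorded in the result. Cutting the sample dendrogram
into two clusters gives a purity score (best label-to-cluster assignment);
a purity that fails to beat the majority-class fraction by more than 0.05 is
flagged as uninformative. Correlation distance needs enough genes to be
meaningful — with a 2-gene signature every centered profile is ±perfectly
correlated, so cluster on a reasonable superset (e.g. the top 10 ranked
genes) when the chosen signature is very small, or switch to Euclidean
distance. `write_report` assembles the stage outputs into one JSON document
(metrics rounded to 3 decimals, as conventional) and fails loudly if any
stage output is missing; reruns under the same seed are identical up to the
timestamp.

## Known limitations

* Mutual information uses plug-in estimates on three states; no bias
  correction, no continuous-variable estimators.
* LOOCV only (the design the evaluation protocol specifies); no k-fold
  option is wired into the pipeline wrapper.
* The SMO solver targets the small-n regime of cohort studies (hundreds of
  samples); it precomputes the kernel per fold and is not meant for
  thousands of samples.
* The plateau rule, although a faithful formalization, can differ from a
  human judgment call on curves with long shallow ascents; both the chosen
  and the argmax size are always reported so the curve can be re-read.
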