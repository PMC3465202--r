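---
title: "Beam-search gene-subset selection: model, parameters, and design notes"
author: "genebeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-search gene-subset selection: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression-based tumor classification works with a samples x genes matrix
`X = (x_ij)` of `m` labeled samples over `n` genes, with `n >> m` (thousands
of genes, tens of samples). Two goals conflict: find gene subsets `T` that
classify as accurately as possible, and keep `|T|` as small as possible —
both because small subsets are interpretable and usable as diagnostic
panels, and because the curse of dimensionality punishes large feature sets
on small cohorts. A useful guideline is that the per-class training-sample
count should exceed five times the feature count, so a 2-class cohort of 80
samples supports at most `floor(80 / (5 * 2)) = 8` genes
(`recommended_max_subset_size()`).

Exhaustive search over subsets is infeasible (`2^n` candidates, and the
problem is NP-complete in general), so `genebeam` implements a wrapper
strategy: a nonparametric filter shrinks the gene pool, then a beam search
grows subsets one gene at a time, scoring each candidate by cross-validated
classifier accuracy.

## The pipeline

1. **Prefilter** (`kwrst_pvalues()`, `preselect()`). Every gene is scored by
   the tie-corrected Kruskal-Wallis rank sum test across classes (for two
   classes this equals the two-sided normal-approximation Wilcoxon test).
   The `p` smallest-p genes (default 300) form the candidate pool. The
   chi-square approximation to the H statistic is used rather than exact
   small-sample tables: only the ranking matters downstream, and the
   approximation is standard. Equal p-values are broken by original column
   index so the pool is deterministic.

2. **Beam search** (`hbsa()`). Layer `i` of the search holds gene subsets of
   size `i`. Layer 1 evaluates all `p` singletons (the beam always holds all
   `p` at layer 1, whatever the beam width `w`). Each subsequent layer forms
   the classification matrix `CM` with entries
   `a_ij = Acc(Row[i] + Column[j])` — the cross-validated accuracy of the
   i-th beam subset extended by the j-th candidate gene — and keeps the `w`
   highest-scoring *open* cells as the next beam. Cells that do not grow the
   subset, or whose union was already scored on another path (*closed
   nodes*), carry a negative sentinel and are never expanded; a registry
   guarantees no subset is ever evaluated twice, which also subsumes the
   symmetric-first-layer optimization (only unordered pairs cost an
   evaluation). The search stops when a layer's best accuracy reaches
   `acc_max`, when the layer index reaches `depth`, when the best accuracy
   plateaus within an optional `delta`, or when the beam exhausts. All
   final-layer top-`w` subsets are returned; an optional tolerance `tau`
   restricts them to within `tau` of the best, off by default.

3. **Evaluation** (`cv_accuracy()`, `full_fold_cv()`). `Acc(T)` is pooled
   stratified k-fold CV accuracy (fraction of all samples predicted
   correctly out of fold; the fold count is 10 by default), with one fixed
   seeded partition per search run so the layer trace is coherent. Wrapped
   classifiers: Euclidean 5-NN (odd k avoids binary vote ties; multi-class
   ties go to the nearest neighbor among the tied classes), or an RBF-kernel
   SVM whose accuracy is the maximum over a (C, gamma) grid — C in
   {200, 400}, gamma in {a x 10^e : a = 1..9, e = -5..-1} plus {1..10}.
   Full-fold CV runs every fold count k = 2..m and summarizes the CV(k)
   sequence by its mean (denominator m - 1) and standard deviation
   (denominator m - 2); subsets that score well across all fold counts are
   robust to the bias/variance trade-off of any single k.

4. **Ensemble** (`ensemble_predict()`, `confidence()`). One individual
   classifier per optimal subset, each trained on the full training set
   restricted to its subset; test samples are predicted by simple majority
   vote. The confidence level of a vote vector is `m_max / m_sec` (largest
   over second-largest count), set to the ensemble size N when the vote is
   unanimous, so it always lies in [1, N]. For cross-platform test sets,
   `shared_subsets()` first drops members whose genes the test platform does
   not measure.

5. **Ranking** (`gene_frequency()`, `powerlaw_fit()`,
   `accuracy_vs_topk()`). Genes are ranked by how many optimal subsets they
   occur in, accumulated over all supplied runs; frequency ties break by
   Kruskal-Wallis p, then gene id. The log-log regression of frequency on
   rank is the power-law diagnostic: near-linearity (r-squared close to 1)
   means few genes dominate the subsets, which is what makes short
   diagnostic panels possible. The top-k accuracy curve retrains the
   classifier on the k most frequent genes; genes missing from a test
   platform are skipped with the next rank substituted, and the
   substitutions are reported.

6. **Enrichment** (`hypergeom_p()`, `binomial_p()`). Over-representation of
   selected genes in a pathway of M genes out of a universe of N:
   the exact hypergeometric tail, and its binomial approximation
   `P(X >= x)`, `X ~ Binomial(K, M/N)`, appropriate for large universes.
   Both tails are exposed; the default is the upper tail (enrichment), with
   the lower tail available for depletion questions.

## Biased versus unbiased evaluation

For the SVM, several (C, gamma) pairs often tie for the best training-CV
accuracy while predicting the test set differently. *Unbiased* mode resolves
the tie deterministically by grid order (gamma ascending, then C ascending)
using training data only — the honest generalization estimate. *Biased* mode
resolves it by test accuracy; per classifier, its test accuracy is therefore
at least the unbiased one by construction. The gap between the two measures
how much optimism test-set feedback injects. At the voted-ensemble level the
ordering holds on average but is not a theorem: majority voting is not
monotone in member accuracy, and isolated draws can invert it slightly —
the test suite asserts the per-classifier ordering draw by draw and the
ensemble ordering in the mean. Biased results are labeled as such in all
outputs. k-NN has no tuned hyperparameter, so biased mode does not apply.

## Normalization

Per-gene z-scoring (mean 0, sd 1, denominator m - 1) is the default; 0-1
min-max scaling is provided as an alternative. Because column-wise
normalization commutes with column subsetting, normalizing the whole
training matrix once before the search is identical to re-normalizing each
restricted gene block at evaluation time; the pipeline normalizes once.
Train and test sets are normalized independently by default. Normalizing
inside each CV fold (training statistics applied to the held-out fold) is
available as `normalize = "per_fold"` but off by default, matching the
convention of normalizing the training set once up front. Constant gene
columns map to 0 (z-score) and 0.5 (min-max) to avoid division by zero.

## The synthetic-data generator

`simulate_expression()` emulates a microarray-style cohort with known ground
truth: noise genes are Normal(0, sigma) identically across classes;
each planted informative gene receives class-specific means spaced `effect`
units apart, with the class-to-mean assignment permuted per gene so
multi-class structure is not symmetric; optional gene blocks share a latent
factor giving pairwise correlation `block_rho`. Defaults (2 classes, 30
samples per class, 200 genes, 4 informative at 3 sigma) represent a
well-powered two-class cohort with a handful of strong markers.
`simulate_cross_platform()` draws new samples from the same class model,
keeps a random fraction of gene ids, applies an affine distortion and adds
platform-only genes — emulating a second microarray platform with partial
gene overlap.

The model is deliberately Gaussian even though real expression data are
heavy-tailed and dependence-rich (a log-normal-tailed noise option exists
for robustness checks): ground truth must be known exactly for
parameter-recovery tests, and the rank-based prefilter is
distribution-free anyway. Passing tests on these simulations therefore
demonstrates correctness of the machinery and recoverability of planted
signal — not performance on any real cohort, where correlated genes,
batch effects and label noise make accuracy claims dataset-specific.

## Numerical and design choices

- **Sentinel**: closed/invalid CM cells store a negative value, never 0, so
  they cannot collide with a genuinely 0-accuracy open subset; traces never
  show sentinels.
- **Beam tie-breaks**: accuracy descending, then the sum of members'
  prefilter ranks ascending (prefers stronger marginal genes), then the
  lexicographic gene tuple — the beam is fully deterministic given the seed.
- **Trace monotonicity**: the per-layer best accuracy usually rises, but
  adding a gene can lower CV accuracy; a decrease is reported as a message
  rather than silently accepted or asserted away.
- **Stopping at layer 1**: if a single gene already reaches `acc_max` the
  search returns singletons — the minimal-size objective takes precedence.
- **Folds**: stratified, dealt round-robin within class after a seeded
  shuffle, with the deal continuing across classes so fold sizes balance;
  one partition per run (k-NN runs are repeated over seeds via
  `multi_run_hbsa()` to average out partition effects; frequencies
  accumulate per run).
- **k-NN engine**: the k-fold CV inner loop runs on a precomputed
  squared-distance matrix in C++; extending a subset by one gene updates the
  matrix by addition, so a search evaluation costs O(m^2) rather than a
  full re-computation. The exported `knn_predict()` implements the same tie
  rule in R.
- **AUC**: midrank formula (ties count one half), identical to the
  trapezoidal ROC area.
- **Degenerate inputs**: constant genes get Kruskal-Wallis p = 1; rates with
  zero denominators are `NA`, never 0; an empty gene intersection or an
  ensemble with no shared subsets is an error, not a silent fallback.

## Problem sizes used by the test suite

The suite exercises the full stack at desk scale, chosen so each property
is non-degenerate: oracle-equivalence runs use 6 candidate genes (all
C(6,3) subsets enumerable exactly), parameter recovery uses 60 samples x
200 genes with 4 planted markers at 3 sigma over 10 seeds, and the
bias-ordering experiment uses 20 independent train/test draws with a
10-classifier ensemble over a reduced (C, gamma) grid that preserves the
tie structure the phenomenon depends on. Search parameters at full scale
(p = 300, w = 300, depth = 15) are configuration defaults; nothing in the
implementation depends on the scale.

## Known limitations

- The wrapper objective reuses one CV partition per run; accuracies are
  optimistic relative to nested CV, which is intentional — quantifying that
  optimism is what the biased/unbiased contrast and the independent test
  set are for.
- The SVM grid maximum makes `Acc(T)` non-decreasing in grid size, so
  accuracies are comparable only under a fixed grid.
- No probe-level modeling, batch correction, or pathway-database access;
  enrichment takes the count inputs directly.
- Full-fold CV costs m - 1 cross-validations per subset and is meant for
  the final subset collection, not as the search objective.
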