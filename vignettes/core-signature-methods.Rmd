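---
title: "Methods: consensus signature discovery, PCA separation testing, and metagene scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus signature discovery, PCA separation testing, and metagene scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresig)
```

## The problem

Independently published gene signatures for one phenotype — tumour-cell
motility and invasion in the motivating application — agree poorly, and
each list is contaminated by platform- and study-specific false positives.
`coresig` operationalizes a simple consensus principle: a gene reported by
many independent signatures is more likely a genuine marker than a gene
reported once. The package covers the full arc: overrepresentation
discovery against a randomization null, class-separation validation on
labeled expression data, and a portable metagene score, plus generators for
synthetic data that make every step testable without external downloads.

## Overrepresentation model

Let the collection be signatures $S_1,\dots,S_m$ (deduplicated sets of
uppercased symbols) and the universe $U=\bigcup_i S_i$. The *multiplicity*
of a gene is the number of signatures containing it. `observed_frequencies()`
tabulates exact counts $O_k$ (genes in exactly $k$ signatures) and
cumulative counts $O_{\ge k}$.

The null model (`sample_random_collection()`) redraws each list uniformly
without replacement from $U$, preserving the number of lists and their
sizes; `expected_frequencies()` averages the resulting exact counts over
`replicates` draws (default 1000 — the historical procedure used a single
matched draw, which is an unstable estimate; `replicates = 1` reproduces
it). Sampling is uniform; no attempt is made to weight genes by their
observed frequency, which is what "randomly selecting genes from the gene
universe" means operationally.

`chi_square_gof()` compares the exact-count distributions with Pearson's
$X^2=\sum_k (O_k-E_k)^2/E_k$ over multiplicities $k\ge 2$ (singletons carry
no repetition information), pooling tail bins until the pooled bin has
expected count $\ge 5$ — the standard validity rule; the binning is
otherwise not prescribed by the original procedure. Degrees of freedom are
bins minus one.

`select_core_signature()` then applies the selection rule: a multiplicity
$k$ *qualifies* when $O_{\ge k} > E_{\ge k}$; the threshold $k^*$ is the
qualifying $k$ with the largest observed cumulative gene set (cumulative
counts are non-increasing, so this is the smallest qualifying $k$; ties go
to the smaller $k$ by the same logic); the core is every gene with
multiplicity $\ge k^*$. Selection is gated on chi-square significance at
`alpha` (default 0.05). The printed per-multiplicity counts the package
ships as a fixture (646, 202, 62, 16, 6, 3 observed vs 1065, 376, 87, 14,
1, 1 expected at $k=2..7$) are read as *cumulative* counts: under that
reading — and only under it — the rule selects $k^*=5$ and a 16-gene core
matching the published consensus list, which is why the cumulative reading
is the package default. Exact counts are always derivable and reported.

### Calibration caveats (important)

Two properties of this rule deserve explicit statement, because the test
suite measures them honestly:

* **The null is not exchangeable.** The universe of a collection is defined
  as the union of its member lists. A random collection redrawn from that
  union concentrates on a smaller frame than the one that generated the
  collection, so redraws show *more* repetition than the original at low
  multiplicities. Consequently the chi-square gate fires almost always for
  large collections — including the shipped worked example, whose expected
  count at $k=2$ (1065) far exceeds the observed 646 — and the gate
  contributes little type-I control. The residual false-discovery rate of a
  non-empty core on pure-random collections is governed by the qualifying
  condition alone and measures around 10–20% at realistic scales, mostly
  from single observed genes at high multiplicity beating fractional
  expected counts. Treat a *marginal* core (small excess over expectation at
  $k^*$) with suspicion.
* **Recall is guaranteed, precision is not.** For a planted core at high
  inclusion fraction, $k^*$ never exceeds the minimum planted multiplicity,
  so every planted gene is recovered. But because planted genes inflate the
  observed cumulative count at *every* $k$ below their multiplicity,
  qualification begins while the null still produces a handful of
  bystander genes at $\ge k^*$; those enter the core. In simulations at the
  default scale (published signature sizes, 2000-gene universe, 10 planted
  genes at fraction 0.8 of 20 signatures) the selected core has median size
  11.5 and perfect precision in only ~40% of seeds. The selected set should
  be read as a high-recall superset of the consensus, not an exact
  recovery.

## Separation testing

`signature_pca()` standardizes each signature gene to mean 0 / variance 1
across samples (`scale = FALSE` gives covariance PCA instead — loadings on
heterogeneous-variance genes differ, so both conventions are exposed) and
computes sample scores and gene loadings; PC1 is sign-oriented so its
scores correlate non-negatively with mean standardized signature
expression, making loadings comparable across datasets. Genes are matched
to feature ids case-insensitively and the submatrix is sorted by feature id
so that results are bit-reproducible regardless of input gene order.
Zero-variance genes are dropped with a warning; if *all* genes are
degenerate the embedding is all-zero, so fully identical samples yield a
centroid distance of 0 rather than an error.

`centroid_distance()` is the Euclidean distance between the two class mean
points in the first two components ("2D-scatter" convention; the component
count is configurable). Two nulls qualify an observed distance:

* `permutation_test()` shuffles class labels (sizes preserved) on the fixed
  embedding. Refitting the PCA per permutation would be a no-op — the
  embedding is unsupervised and unchanged by relabeling — so the package
  does not offer it. The p-value uses the plus-one rule
  $p=(1+\#\{d_{null}\ge d_{obs}\})/(1+N)$, hence never 0; $N=100$ by
  default.
* `random_geneset_baseline()` redraws equally sized gene sets from the
  universe (restricted to measured, non-degenerate features) and reruns the
  *full* PCA + distance pipeline per set, answering a different question:
  does this particular gene set separate the classes better than arbitrary
  sets from the same pool?

## Filters for multi-dataset expression input

* `intensity_filter()`: keep features above `log2(100)` in at least
  `ceiling(0.10 * n)` arrays (defaults as published; both tunable). The
  rule is strict `>` on intensity and is idempotent.
* `collapse_probes()`: one row per gene; default representative is the
  probe with the highest mean intensity (an explicit, deterministic
  convention — the original procedure is silent here), `method = "median"`
  gives per-sample medians instead.
* `align_common()` + `consistency_filter()`: on the sample/feature
  intersection (sample ids matched case-insensitively after exact
  string folding — no fuzzy cell-line matching), compute per feature the
  $D(D-1)/2$ pairwise Spearman correlations (midranks for ties) across
  shared samples and keep features with median $\ge 0.50$. Undefined
  correlations from constant features count as 0, deliberately
  conservative: a degenerate probe cannot pass the filter.

## Metagene model and scoring

`fit_loadings()` records each gene's PC1 loading per training dataset
(absent genes stay absent, never zero-filled). `build_model()` takes the
per-gene median over available datasets as the weight and flags a gene
*robust* when its loading range does not straddle zero; single-dataset
genes are robust by convention but flagged `single_source`, so callers can
exclude them if they prefer a stricter reading. `score_samples()` computes
$\mathrm{score}(j)=\sum_g w_g z_{gj}$ over robust genes present in the
dataset ("informative genes only"; `robust_only = FALSE` uses all model
genes). Standardization is the package's choice of scale — the historical
description does not state one — and makes scores invariant to per-gene
affine transforms; missing genes are dropped *without* renormalizing
weights, since scores are only comparable within a dataset anyway. With a
single training dataset the score reproduces that dataset's PC1 scores to
numerical precision, which the tests assert at 1e-9.

`trend_test()` is Spearman correlation with its two-sided p-value (exact
for small tie-free samples, t-approximation otherwise). `group_test()` is
Kruskal-Wallis with tie correction; the default post-hoc is pairwise
Wilcoxon tests with Holm adjustment — "Tukey HSD after Kruskal-Wallis", as
historically described, mixes a rank test with a parametric range
statistic, so the parametric Tukey variant is offered only as an explicit
option (`posthoc = "tukey"`).

## Synthetic worlds

The generators state the conditions the package is tested under:

* `simulate_signature_collection()`: 21 lists whose sizes default to the
  published collection's sizes (3209 membership slots, resampled when a
  different count is requested) over a 2636-gene universe; each planted
  core gene enters each signature independently with probability
  `core_multiplicity_fraction` (0.8 default), remaining slots drawn
  uniformly. Truth is returned for recovery tests.
* `simulate_expression()`: log2-scale Gaussian noise (SD 1) around baseline
  8 — typical of normalized microarray intensities — with an additive
  class shift in signature genes; ~15 samples per class mirrors the
  cell-line panels the method was validated on. Optional low-baseline decoy
  features sit below the intensity threshold by construction.
* `simulate_dataset_family()`: one latent matrix observed several times
  with per-dataset noise (SD 0.5), default 21 shared samples (11 + 10),
  plus a configurable fraction of features rescrambled per dataset as
  consistency-filter targets.
* `simulate_timeseries()`: an 8-point 0–72 h exposure course, two
  replicates per timepoint, signature means rising linearly (default slope
  0.02 log2-units/h ≈ 1.4 units over the course, a realistic
  transition-induction magnitude at noise SD 1).

What these worlds do **not** emulate: probe-level cross-hybridization,
batch and platform effects, heavy-tailed or count-based noise, correlated
co-expression structure beyond the planted factor, and survival outcomes.
A green test therefore establishes algorithmic correctness and statistical
calibration under idealized Gaussian conditions, not performance on raw
public repositories; the published per-dataset centroid distances are not
reproducible without those repositories' raw data and exact preprocessing
and are out of scope.

## Numerical choices

* Chi-square tail pooling threshold 5; degenerate (zero-expected) unpooled
  bins are an error rather than silently skipped.
* Permutation/baseline p-values use the plus-one rule; replicate counts
  default to 100, matching the published procedure.
* Gene submatrices are sorted before PCA; PC1 orientation follows the
  mean-expression convention; trailing degenerate components are
  zero-padded.
* Ties in multiplicity selection go to the smaller threshold (the larger
  or equal gene set).
* Model JSON is written with 17 significant digits, so serialization
  round-trips doubles bit-identically.
* Monte-Carlo-heavy test blocks run the expected-frequency null at 100
  replicates rather than the API default 1000 to stay inside the suite's
  time budget; the Monte-Carlo standard error of the expected counts is an
  order of magnitude below the sampling spread of a single observed
  collection, so verdicts are unaffected.

## Known limitations

The selection rule's calibration caveats above are the main ones. Beyond
those: the consistency filter requires shared samples across datasets (no
correlation across disjoint cohorts); probe collapse by max-mean can pick a
saturated probe; and the metagene score is a relative quantity — comparing
absolute scores across datasets requires the same preprocessing, which the
package does not enforce.
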