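---
title: "Manifold-aware genetic-algorithm gene selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manifold-aware genetic-algorithm gene selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoga)
```

## The problem

Microarray and related expression studies sit in the "large p, small n"
regime: tens of samples, thousands of genes. Most genes are irrelevant to
the phenotype, and their inclusion degrades classifiers. `isoga` implements
a wrapper feature-selection framework for this regime built on three ideas:

1. **Manifold-aware fitness.** A candidate gene subset is judged by how
   clearly the classes separate after embedding the samples — restricted to
   those genes — with Isomap, a nonlinear dimensionality reduction that
   applies classical multidimensional scaling (MDS) to geodesic distances
   estimated on a k-nearest-neighbour graph. Expression profiles are
   assumed to lie near a low-dimensional nonlinear manifold; Euclidean
   distances in gene space misrepresent separation along that manifold,
   geodesic distances respect it.
2. **Classifier-free scoring.** Separation is scored with the
   Davies–Bouldin (DB) index: with per-class centroids $\mu_i$, mean
   within-class distances $S_i$, and centroid separations
   $M_{ij} = \lVert\mu_i - \mu_j\rVert$,
   $$\mathrm{DB} = \frac{1}{C}\sum_i \max_{j \ne i}
     \frac{S_i + S_j}{M_{ij}},$$
   lower being better. Using a cluster-validity index instead of a
   classifier's accuracy avoids tying the selection to one classifier.
3. **Non-randomness aggregation.** A fixed-cardinality genetic algorithm
   (every individual is a set of exactly $m$ gene indices) minimises the DB
   fitness once per stratified bootstrap bag. Under the null that search
   output is random, a gene's selection count over $B$ bags is
   $X \sim \mathrm{Binomial}(B,\, m/p)$. The final set keeps genes whose
   count reaches the smallest $c$ with $P(X \ge c) < \alpha$ — genes the
   repeated searches agree on beyond chance.

## Pipeline and parameters

`iso_ga_select()` runs, in order: intrinsic-dimension estimation, Isomap
neighbourhood tuning, bootstrap bagging, per-bag GA search with out-of-bag
validation, and binomial aggregation.

**Embedding dimension `d`** is estimated once per training set with the
Levina–Bickel maximum-likelihood estimator: the inverse dimension estimate
at neighbourhood size $k$ is the mean over points of
$\frac{1}{k-1}\sum_{j<k}\log(T_k/T_j)$ (with $T_j$ the distance to the
$j$-th neighbour), point estimates are combined by inverse averaging and
then averaged over $k \in [5, 12]$. The estimate is rounded, floored at 1,
and capped at $\min(n-2,\, m-1)$; the cap keeps the embedding meaningful
for $m$-gene subsets. The estimator's neighbour range is a package default
(the estimator's literature offers no single canonical choice) and is
exposed in `run_config()`.

**Neighbourhood size `k`** is tuned by grid search over 5–20 (clipped to
$n-1$): the `k` minimising the DB index of the full-matrix Isomap embedding
wins, ties to the smaller `k`. Values whose neighbourhood graph is
disconnected are skipped. Inside the GA, a disconnected candidate graph
maps to fitness $+\infty$ rather than silently embedding the largest
component: dropping samples would change $n$ between candidates and make
DB values incomparable.

**GA budget.** Defaults are population 100, 100 generations, tournament
size 2, mutation probability 0.01 per selected index, elitism 1 — typical
settings for subset-selection GAs; all are configurable, and the bundled
experiments use reduced budgets (see below). The crossover keeps the
parents' common genes and fills the remaining slots uniformly from the
symmetric difference, preserving cardinality by construction. The engine
*minimises* fitness; "best individual" always means smallest DB.

**Validation pick.** After each bag's search, the best 10 distinct
finalists are re-scored by the out-of-bag accuracy of a fixed RBF-SVM
(median-distance kernel width, unit cost), and the most accurate finalist
becomes that bag's subset. The inner SVM is deliberately untuned: tuning
10 candidates per bag inside every outer fold would multiply cost for a
choice the aggregation step largely washes out.

**Threshold.** `selection_threshold()` computes $c$ with a floor of 2: a
gene seen once can never be distinguished from chance. For subset size 30,
ten bags, $\alpha = 0.05$ this reproduces the whole published table of
per-dataset thresholds (gene counts 70 → 8, 136 → 5, 668 → 3, 982/996/2153/
5194/9564 → 2), the last of those via the floor.

## Preprocessing

`preprocess_expression()` applies, in a fixed order: removal of genes with
missing values, removal of constant genes, per-gene standardisation
(sample standard deviation by default; the convention is configurable and
pinned for reproducibility), and removal of genes with zero information
gain. Information gain uses Fayyad–Irani MDL discretisation by default
because the MDL acceptance test yields "no admissible split", hence a gain
of exactly zero, for label-independent genes — an equal-frequency binning
(the configurable alternative) almost never produces exact zeros.
Standardisation returns its training statistics so held-out folds are
standardised with training parameters only. Outlier samples are *flagged*
(count of |z| > 6 entries per sample) but never removed automatically;
no principled removal rule is part of the contract, so the decision is
left to the analyst.

## Evaluation

`nested_cv_evaluate()` wraps selection in stratified 5-fold outer
cross-validation. Per fold: the training portion is standardised, selection
runs on it alone, classifiers (RBF-SVM via libsvm, and a two-hidden-layer
neural network trained with resilient backpropagation with weight
backtracking, written in-package because no installed R package trains a
two-hidden-layer MLP) are tuned by 2×3-fold stratified cross-validation on
the default grids (kernel width 0.001–0.091, cost 1–10; hidden layers
10–30 and 4–20), and metrics are computed on the untouched test fold. The
`audit` element records index sets so the no-leakage property is checkable
on every run, and the test suite asserts it.

Multiclass scoring uses one-vs-rest AUC with midrank tie handling:
macro-AUC averages per-class AUCs; micro-AUC pools all (sample, class)
indicator/score pairs into one binary problem. For binary problems the
macro average equals the standard AUC; the pooled micro average compares
scores across the two probability columns and can differ — both are
reported, as neither aggregation dominates. `ranking_score()` combines,
per method, its mean-rank over datasets and metrics with its summed
subset-size rank; lower is better. The printed normalisation of the score
is read per-method (a method-independent normaliser would make the score
constant), matching how such summary tables are used.

## Synthetic data

`generate_expression()` emulates the target regime: `m_info` informative
genes trace a one-dimensional curve per class — classes occupy disjoint
parameter intervals, lifted by spiral coordinates and random sinusoidal
harmonics, with Gaussian noise of standard deviation `sigma` — and the
remaining genes are independent standard Gaussian noise, with gene order
permuted. A one-dimensional curve per class (rather than a full
two-dimensional sheet) keeps the intrinsic dimension low enough for the
estimator, the embedding, and the DB index to operate as intended at
$n \approx 60$. Harmonic lifts are rejection-sampled until the
between-class/total spread ratio reaches 0.5, so every planted gene
genuinely carries class signal (a harmonic whose class intervals alias to
overlapping values would be informative in name only).

What the generator does **not** emulate: probe-level artefacts, batch
effects, gene–gene correlation among noise genes, heavy-tailed expression
distributions. Passing the bundled experiments therefore demonstrates the
machinery is correct and recovers planted structure under the stated
model; it does not by itself certify performance on real microarray data.

## Bundled experiments and problem sizes

The test suite and `scripts/acceptance.R` rerun, among others:

- the binomial threshold table (exact, milliseconds);
- shortest-path, MDS, and Isomap oracle checks (exhaustive enumeration up
  to $n = 7$; closed-form reconstructions at tolerance $10^{-8}$);
- DB agreement with an independent textbook implementation ($10^{-9}$ on
  100 random labelled point sets);
- GA optimality on an exhaustively enumerable instance ($p = 20$,
  $m = 3$, 20 seeded runs);
- the Isomap/MDS linear-limit equivalence: on data confined to an affine
  subspace with $k = n-1$, geodesic and Euclidean distances coincide, so
  the two ablations must give identical fitness ($10^{-6}$) — the testable
  core of the Isomap-vs-MDS comparison;
- planted-gene recovery: five replicates of (generate with seed $s$,
  select with seed $s$) on $n = 60$, $p = 300$, 10 informative genes,
  with a reduced GA budget (population 30, 30 generations, 10 bags);
  the mean fraction of the selected set that is planted is the headline
  number, with a label-permuted run as negative control. Replicating the
  *data draw* matters: any single $n = 60$ draw contains a few noise genes
  that correlate with the labels by chance and are selected consistently
  by any correct search — averaging over draws, not merely over search
  seeds, separates method behaviour from draw idiosyncrasy.

Problem sizes throughout are chosen so the whole suite runs on a laptop
CPU in minutes while every check still exercises the full code path.

## Numerical conventions

- Eigenvector signs in MDS are fixed by making each axis's
  largest-magnitude entry positive; eigenvalues below
  $10^{-12}\max|\lambda|$ are treated as zero, and requested dimensions
  beyond the positive spectrum are zero-padded with a warning.
- Distance ties in the k-NN graph break toward the lower point index;
  GA ties break lexicographically on the sorted index tuple; grid-search
  ties take the first grid row; `tune_k` ties take the smaller `k`.
- Fitness values are memoized per bag on the sorted index tuple.
- All randomness flows from one master seed; bag $b$ uses stream
  `seed + b`, outer fold $f$ uses `seed + 1000 f`.

## Limitations

- Isomap has no out-of-sample extension here; embeddings are only ever
  computed on in-bag samples, which is all the fitness needs.
- The binomial threshold assumes searches are independent and genes
  exchangeable under the null; bags share samples, so the null is
  conservative rather than exact.
- With `m` larger than the number of truly informative genes, each bag's
  subset necessarily carries noise genes; the aggregation step, not the
  single search, is what controls them.
- MDL-based information gain is conservative at very small $n$; a weakly
  informative gene can be filtered. The equal-frequency alternative trades
  that for a near-total loss of exact zeros.
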