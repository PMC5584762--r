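---
title: "Methods: network-neighbourhood enrichment and feature selection for gene essentiality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-neighbourhood enrichment and feature selection for gene essentiality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `essnet`, the
conventions and tunable parameters of each stage, what the synthetic
benchmark does and does not emulate, and the design choices made where more
than one defensible convention exists.

## The model

The pipeline treats gene essentiality as a binary classification problem in
which the feature vector of a gene is the functional profile of its network
context, not of the gene itself. Three ideas are composed:

**Neighbourhood enrichment as features.** For gene $g$, let $G(g)$ be the
set containing $g$ and its direct partners in a protein–protein interaction
network, $n = |G(g)|$. For an annotation gene set $T$ with $M$ members in a
background universe of $N$ genes, the feature value is the upper-tail
hypergeometric probability of the observed overlap $m = |G(g) \cap T|$,

$$S(g, T) = -\log_{10} \sum_{k=m}^{n}
  \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},$$

so a gene wired into a functional module scores highly on that module's
term. The score is a *feature*, not a hypothesis test: no multiplicity
adjustment is applied, and $m = 0$ gives exactly $S = 0$ (the full tail sums
to one). Feature vectors concatenate all GO-term scores followed by all KEGG
pathway scores, in that fixed block order.

**mRMR ranking.** With thousands of correlated term features, relevance
alone over-selects redundant ones. Features are ranked greedily: the next
feature maximises $D - R$, where $D = I(f, c)$ is the mutual information
with the class and $R$ is the mean MI with the already-selected features
(zero at the first step). Exhausting the pool yields the mRMR list; sorting
by $D$ alone yields the MaxRel list.

**IFS with a cross-validated SVM.** Nested prefixes of the mRMR list are
each evaluated by stratified 10-fold cross-validation of a linear SVM,
pooling the held-out confusion counts into one SN/SP/ACC/MCC per prefix
size. The optimal feature count is the smallest $k$ attaining the maximum
MCC. MCC is the selection criterion because the labeled classes are
imbalanced about 1:4, which makes ACC (and either per-class rate alone)
misleading; MCC equals the Pearson correlation between predicted and true
labels and is tested against that identity directly.

## Parameters and conventions

* **Background size $N$** (`make_background(size = )`): defaults to the
  union of network nodes and annotation members — the largest universe on
  which both neighbourhoods and memberships are defined. An explicit
  integer (e.g. a genome-wide gene count of ~20,000) may be supplied
  instead; scores shrink as $N$ grows, but monotonicity in $m$ is
  unaffected.
* **Score cap** (`cap = 320`): $-\log_{10} p$ overflows when $p$ underflows
  double precision; 320 is approximately $-\log_{10}$ of the smallest
  representable double. Whether extreme scores should be capped at all has
  no effect on any rank-based downstream stage.
* **Edge-score threshold** (`read_network(min_score = )`): STRING-style
  exports carry confidence scores in [0, 1000]; the default keeps every
  edge, and a threshold is purely a data-cleaning choice exposed to the
  caller.
* **Discretization** (`discretize_feature()`): MI is estimated on three
  states cut at mean ± population SD, the three-state convention of the
  mRMR literature. Values at or beyond an edge take the outer state;
  strictly interior values the middle one. The outer-assignment rule
  matters: a symmetric two-valued feature has its edges exactly on the two
  values, and sending boundaries to the middle state would collapse such a
  feature to a constant and erase its information. Constant features
  (zero SD) map to the middle state everywhere and carry zero MI.
  MI is reported in bits (log base 2); rankings are invariant to the base,
  which a property test asserts by re-deriving the order in base e.
* **Tie-breaks**: equal $D - R$ (or equal $D$ in MaxRel) resolves to the
  lower feature index, making both lists fully deterministic.
* **Classifier** (`svm_linear_spec()`): a linear-kernel SVM with complexity
  constant 1 and train-fold standardization, matching the common "default
  parameters" configuration of SMO-style SVM tools; `e1071::svm` (libsvm)
  provides the solver. The classifier is pluggable through
  `classifier_spec()`: any `fit`/`predict` pair with the documented
  contract can drive `cross_validate()`, `run_ifs()` and `train_final()`.
* **Fold pooling**: confusion counts are pooled (micro-averaged) across the
  10 held-out folds rather than averaging per-fold metrics, because a
  single SN/SP/ACC/MCC per feature count is wanted and per-fold MCC is
  unstable with ~20 positives per fold. One fold assignment, fixed by a
  seed, is shared by every prefix size so the IFS curve is comparable
  point-to-point.
* **IFS sweep** (`k_min = 5`, `k_max = 500`, `step = 1`): 496 feature sets
  at the defaults. The lower bound avoids degenerate one-feature models;
  the upper bound reflects the expectation that a few hundred terms at most
  separate the classes. Ties on the maximum MCC resolve to the smallest
  $k$ (parsimony).

## The availability filter

Labeled genes absent from the interaction network have no neighbourhood and
hence no enrichment encoding; `filter_unencodable()` drops them (with a
log of who and why) before any matrix is built. A gene *present* but
isolated still has the well-defined singleton neighbourhood $\{g\}$, so by
default it is kept; `mode = "all_zero"` additionally drops genes whose
entire score row is zero, for callers who consider such rows unavailable
too.

## The synthetic benchmark

`generate_dataset()` plants a recoverable signal into an otherwise random
dataset: a background Erdős–Rényi network (`p_background = 0.005`), 500
GO-like and 50 KEGG-like terms with sizes uniform on 10–40 (typical sizes
for specific curated sets), and 200 positive / 800 negative labels echoing
the roughly 1:4 imbalance of curated essentiality gold standards. Each
positive gene is assigned 1–3 of the 20 informative terms and wired to each
of their members with probability `p_signal = 0.5`, so its neighbourhood is
hypergeometrically enriched in exactly those terms; negatives receive only
background wiring.

Two deliberate departures from realism keep the ground truth identifiable:

* positive genes are excluded from all term memberships, so the planted
  signal is purely neighbourhood-mediated rather than an artifact of
  self-membership;
* informative terms draw pairwise-disjoint member sets from a reserved
  slice of the gene pool, and all other terms draw from its complement.
  With freely overlapping memberships, unplanted terms sharing members
  with planted ones become aggregate proxies of the class signal — each
  planted term covers only ~10% of positives, while a proxy can straddle
  several — and the ground truth stops being the right answer to recover.
  Mimicking real term-overlap statistics is explicitly out of scope.

Consequently, passing the recovery tests shows the pipeline finds
neighbourhood-mediated signal under controlled conditions; it does not show
robustness to the heavy term overlap, scale-free degree structure, DAG
redundancy or annotation bias of real GO/KEGG/STRING data. Note also that
the planted wiring raises positives' mean degree above background, so some
class signal leaks into *every* term's feature; the mRMR stage is what
separates the planted terms from this diffuse degree effect.

Problem sizes in the tests are chosen to keep the suite quick: the default
benchmark (1000 genes × 550 terms, full k = 5..500 sweep) is exercised once
for the headline recovery checks, while multi-seed property tests (paired
comparison against random feature subsets over 10 seeds; signal
monotonicity in `p_signal` over 5 seeds) run on reduced configurations of
150–250 genes and a short sweep.

## Numerical and degenerate-input behaviour

* `hyper_score()` delegates the tail sum to `stats::phyper`
  (`lower.tail = FALSE` at $m - 1$) and is pinned against an explicit
  enumeration oracle to $10^{-9}$ in $p$ on random small instances.
* Empty neighbourhoods cannot occur ($g \in G(g)$ always); a term with no
  members inside the universe has $M = 0$, $m = 0$, score 0.
* A training fold reduced to a single class is a hard error, not a silent
  skip — with stratified folds it indicates an infeasible fold count.
* Zero-variance feature columns standardize to constant zero (unit scale)
  rather than dividing by zero.
* An undefined MCC (a zero factor in the denominator) is reported as 0 with
  an explicit `mcc_defined = FALSE` flag rather than `NaN`, so downstream
  maximisation never propagates missing values.
* `which.max`-based argmaxes take the first (lowest-index) maximum,
  implementing the documented tie-breaks exactly.

## Known limitations

* MI uses the plug-in estimator on three discrete states; no bias
  correction, kernel or k-NN estimator is offered.
* The mRMR loop is quadratic in the feature count (all pairwise MI against
  selected features); it is vectorised but not approximated, so very large
  annotation collections (10⁵ terms) would be slow.
* No nested cross-validation tunes the SVM cost; "default parameters" is a
  deliberate convention, and alternative optimality criteria (AUC) are not
  implemented.
* Gene identity is the raw symbol string: no alias resolution, no GO
  ancestor propagation, no identifier mapping.
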