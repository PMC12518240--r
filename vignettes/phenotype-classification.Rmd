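---
title: "Methods: compositional preprocessing, consensus feature selection and dynamic ensemble selection for microbiome phenotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype classification from count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the data model

Amplicon sequencing yields, per cohort, a table of non-negative integer
counts: samples in rows, taxa (ASVs or OTUs) in columns. Counts are
*compositional*: sequencing depth is an instrument artefact, so only relative
information is meaningful, and analyses must operate on the simplex or in a
log-ratio coordinate system. `phenodes` classifies a binary phenotype
(`D`/`NotD`) from such a table and is built around three ideas:

1. respect the compositional geometry (pseudocount → closure → centred
   log-ratio transform; augmentation happens *inside the simplex*);
2. select a small panel of taxa that three unrelated estimator families agree
   on (consensus recursive feature elimination);
3. classify with a *dynamic* ensemble: for every query sample, choose which
   base models may vote based on their competence in that sample's local
   neighbourhood of a held-out reference set (DSEL).

## Module 1: preprocessing

| parameter | default | meaning |
|---|---|---|
| `min_total_counts` | 2500 | inclusive per-sample depth filter ("at least") |
| `pseudocount` | 1 | added to every count before closure; removes zeros so the CLR is defined |
| `top_k_features` | 1500 | features kept, ranked by mean relative abundance |
| `train_fraction` | 0.7 | stratified train share; per-class counts use floor + largest remainder, so 10 D / 20 NotD at 0.7 gives exactly 7 + 14 |
| `p_mask` | 0.5 | Bernoulli probability that a CutMix child takes a feature from its first parent |

Numerical conventions, chosen once and tested:

* **Abundance ranking ties** at rank *k* keep the lexicographically smaller
  feature id. The ranking statistic is the mean relative frequency over all
  samples; prevalence or total counts would also be defensible, but the mean
  relative frequency is deterministic, order-independent and matches the
  "most abundant" reading. The retained columns keep their values — the
  composition is *not* re-closed after the cut, so the discarded mass still
  informs the CLR geometric mean through the pseudocounted remainder.
* The top-k cut is computed on the full cohort *before* the split, following
  the pipeline's stage order (filtering → abundance cut → split). This leaks
  a small amount of unlabelled distributional information into the test set;
  a strict post-split protocol can be emulated by calling
  `top_abundant_features()` on training rows only.
* `clr_transform()` requires strictly positive entries and refuses otherwise,
  pointing at the pseudocount; rows of the result sum to 0 within 1e-9 and
  the map is scale-invariant per row.

## Augmentation: compositional CutMix

Class balancing creates synthetic *minority-class* training samples per
stratum (e.g. collection site): the deficit of each (class, stratum) cell
versus the in-stratum majority is filled by children of parent pairs drawn
uniformly with replacement from that same cell. A child takes each feature
from parent 1 with probability `p_mask`, else from parent 2, and is re-closed
by a single global renormalisation. Consequences we rely on in tests: the
child is strictly inside the simplex whenever its parents are; identical
parents reproduce themselves; a parent paired with itself is a copy (allowed
— that is what sampling with replacement means). The cited method family
leaves the mask law and renormalisation open; Bernoulli(½) with global
closure is the symmetric choice and is config-exposed. A two-part
λ-weighted renormalisation was considered and not implemented.

Augmentation operates on compositions *before* the CLR, and only ever on
training rows. During cross-validation the plan is recomputed inside each
fold from that fold's training part. Test data is never augmented, full stop.
The `downsample` strategy (drop majority rows to the minority count) and
`none` exist as comparators for `compare_imbalance_strategies()`.

## Consensus recursive feature elimination

RFE removes, per iteration, the `max(1, 5% of surviving)` least-important
features (truncated to land exactly on the target) and refits. The three
estimators and their importances:

* random forest — normalised Gini impurity decrease;
* linear SVC — absolute primal coefficients;
* logistic regression — absolute ridge coefficients (glmnet).

The two linear estimators are strongly regularised (`C = 0.01`,
`lambda = 1`). With `p` comparable to `n` — routine after the abundance cut —
weakly regularised coefficient rankings are dominated by noise directions and
the elimination order destabilises; strong shrinkage makes the ranking track
marginal class separation, which is what an elimination order should encode.
Removal-order ties drop the lexicographically later feature id first.

`consensus_select()` scans the shared per-estimator target
`t = NSF, NSF+1, …, t_max` and stops at the first `t` whose three-way
intersection has exactly `NSF` members. By default each estimator's full
elimination ranking is computed once and the size-`t` set is its top-`t`
prefix. Prefixes are nested, so the intersection size is non-decreasing in
`t`; the scan is therefore monotone, and overshooting `NSF` *proves* the
consensus unattainable — the error carries the full `(t, intersection size)`
trace. This mirrors the empirical phenomenon that some NSF values have no
consensus at any target. `reuse_ranking = FALSE` refits RFE at every `t`
(the literal protocol; slower, and the scan is then heuristic rather than
provably monotone). The pipeline logs and skips unattainable NSFs.

## Module 2: the model pool and dynamic ensemble selection

Five base families are implemented natively (see "implementation notes") and
tuned by exhaustive grid search under stratified 10-fold cross-validation,
scored by ROC AUC — appropriate under class imbalance, where both error types
are costly. Ties take the earlier grid entry; the winner is refit on all
provided rows. At final training a stratified 10% of the training rows is
carved out as the DSEL; during cross-validated evaluation each fold's
validation part doubles as the DSEL, matching the 70/20/10
train/test/validation arithmetic of the design.

For a query `q`, the region of competence is its `k` nearest DSEL rows by
Euclidean distance in the consensus-feature CLR space (default `k = 7`,
tunable over `{3,5,7,9,11}` by held-out AUC with smallest-`k` tie-break;
distance ties break by DSEL index). With `corr[m, j]` the 0/1 correctness of
model `m` on neighbour `j`:

* **DES-P**: select `m` with `mean(corr[m, ]) − 1/2 > 0`. The inequality is
  strict — a model exactly at chance is *not* better than random.
* **KNORA-E**: select `m` with all `k` neighbours correct; while none exists
  and `k > 1`, drop the farthest neighbour and retry.
* **KNORA-U**: select `m` with ≥ 1 correct neighbour, weight = number of
  correct neighbours.
* **DES-C**: seeded k-means partition of the DSEL (default 5 clusters); in
  the query's nearest non-empty cluster keep the top `ceil(0.5 · M)` models
  by accuracy, then greedily keep `ceil(0.33 · M)` by diversity, where
  pairwise diversity is 1 − double-fault rate (the fraction of cluster
  samples both models misclassify). The greedy selection is seeded from the
  most accurate model; ties prefer higher accuracy, then lower model index.

When a rule selects nothing (possible for DES-P, KNORA-E at `k = 1`, and
KNORA-U), the decision falls back to the whole pool with uniform weights and
the decision is flagged — the rules are total functions. The combination is a
weighted majority of hard votes (threshold 0.5); a vote tie resolves to the
label with the higher weighted mean probability, and a residual tie to
`NotD` (the conservative, "no diagnosis" default). The ensemble score is the
weighted mean of the selected models' P(D), so downstream ROC analysis treats
ensembles and base models identically.

## Evaluation and ROC-curve comparison

Cross-validation metrics are computed on *pooled* out-of-fold predictions
rather than averaged per fold: per-fold AUC is unstable at fold sizes of a
few dozen samples. F1, precision and recall use `D` as the positive class
with the zero-denominator convention (undefined → 0). The AUC is the
trapezoidal area with simultaneous steps at tied scores, i.e. the
Mann–Whitney statistic with half credit for ties; tests verify exact
agreement with brute-force pair counting.

Two permutation tests compare ROC curves. Both are rank-based (invariant to
monotone score transforms) and use the add-one estimate
`p = (1 + #{permuted ≥ observed}) / (1 + B)`, `B = 999` by default, so `p`
is never 0 and never below `1/(B+1)`.

* **Paired** (same samples, two score vectors): each vector is
  rank-transformed; at every rank cutoff `c` the misclassification count
  `e(c) = FP(c) + FN(c)` is compared and the statistic is
  `Σ_c |e_A(c) − e_B(c)| / n²`, zero iff the empirical curves coincide. The
  null swaps each sample's pair of ranks independently with probability ½ and
  re-ranks. Score ties are broken by sample index — deterministic, at the
  cost of an arbitrary but fixed ordering of exactly tied scores.
* **Unpaired** (independent samples): each group's `sensitivity +
  specificity` curve is evaluated at every pooled score cutoff and the
  statistic integrates the absolute difference; the null permutes group
  membership within each class, leaving pooled ranks untouched. Evaluating at
  score cutoffs (comparisons only) rather than integer pooled ranks keeps the
  statistic exactly 0 when the identical sample is passed as both groups.

Under a simulated exchangeable null the paired p-values are uniform
(Kolmogorov–Smirnov check in the acceptance suite); both designs reject a
strongly separated marker against noise at `p ≤ 0.01`. Multiple-testing
control is left to the caller (pairwise p-values are reported raw; a Holm
adjustment is one `p.adjust()` call away).

## The synthetic generator: what a green test establishes

`generate_table()` draws a base composition from a heavy-tailed log-normal
(σ = 1.5, mimicking real rank-abundance curves), multiplies the
`n_informative` planted taxa by `exp(±effect/2)` per class, adds per-sample
log-normal noise (σ = 0.5), re-closes, imposes class-independent structural
zeros (Bernoulli thinning, default 30%), and samples counts multinomially at
a depth drawn uniformly from `library_size_range` (default 5,000–50,000).

Presets: `signal` (300 × 200, effect 4, 40% minority — a cohort a strong
classifier should nearly solve), `null` (800 × 150, effect 0 — label-free;
the cohort is sized so that a chance-level test AUC estimate, whose sampling
SD is about `sqrt((n₊+n₋+1)/(12 n₊ n₋)) ≈ 0.04` at a 240-sample test set,
stays inside a ±0.1 band around 0.5 across seeds; this was fixed by that
power argument before any acceptance run), and `pd_like` (imbalanced,
two-site stratum, for exercising per-stratum balancing).

The generator emulates sparsity, depth heterogeneity, class imbalance,
strata and planted log-fold effects. It does **not** emulate phylogenetic
correlation between taxa, batch or site effects on non-informative taxa,
overdispersion beyond the log-normal–multinomial hierarchy, or taxa
co-occurrence networks. A green end-to-end test therefore establishes that
the machinery is correct and leakage-free on data with those stated
properties — not that any particular real cohort will reach a given AUC.

## Implementation notes and limitations

* The base learners are native implementations: random forest and
  second-order gradient-boosted trees in C++ (Gini / Newton-gain CART,
  deterministic given seeds), a primal squared-hinge SVC (linear and RBF via
  the representer form) with Platt-calibrated probabilities, a small
  fully-connected network with Adam and early stopping, and kNN on top of
  FNN's neighbour search. They follow the standard algorithms but are not
  numerically interchangeable with other stacks' implementations; the
  package's claims are about the pipeline's behaviour, which the test suite
  checks against independent oracles, not about bit-parity with any
  particular library.
* Every stochastic step derives its seed from the run configuration
  (`seed`, `partition_seeds`, and per-NSF derived seeds), so a rerun with the
  same configuration is byte-identical, including the on-disk metrics tables
  and the JSON manifest — the manifest deliberately contains no timestamps.
* Model selection across NSFs is reported both ways: the NSF-averaged tables
  include cross-validation and test splits. Selecting "the best" model on
  test-set averages is how the comparison tables are conventionally read,
  but it is selection on test data; the cross-validation columns are the
  methodologically clean basis and sit in the same table.
* Binary labels only; dynamic *classifier* selection (single-model) rules and
  meta-learning selectors are out of scope. BIOM is read through biomformat
  (JSON and HDF5); TSV is the native interchange format.
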