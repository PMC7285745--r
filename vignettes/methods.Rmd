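---
title: "Methods: multilane capsule networks for saliva-secretory protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilane capsule networks for saliva-secretory protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salcaps)
```

## The problem

Proteins secreted into saliva — by the salivary glands directly or via the
circulation — are attractive disease-biomarker candidates because saliva can
be sampled noninvasively. Few proteins are annotated as saliva-secretory,
so the prediction task is a heavily imbalanced binary classification from
sequence alone: given an amino-acid sequence (and, when available, an
evolutionary profile), decide whether the protein is saliva-secretory.

`salcaps` implements the full pipeline: profile encoding, a multilane 1D
capsule network, bagging-ensemble training for class imbalance, threshold
selection at maximal Matthews correlation, signed-confidence ranking of
proteome-wide predictions, and hypergeometric validation of top-ranked
lists against known marker sets. A synthetic-data module generates
motif-implanted benchmark sets so every stage can be exercised and tested
without any external database or profile search.

## Input encoding

Sequences are encoded as an L x 20 matrix over the fixed alphabet
`ARNDCQEGHILKMFPSTWYV` (the ordering of BLAST ASCII PSSM files), either as

* a **normalized PSSM**: raw log-odds scores from a profile search, squashed
  elementwise into (0, 1); or
* **one-hot rows**, with ambiguous residues (B, J, O, U, X, Z) mapped to
  all-zero rows — a neutral signal rather than an invented composition.

The profile-generation tools that produce "normalized" PSSMs do not
document a single normalization formula, so `normalize_profile()` defaults
to the elementwise logistic `1/(1 + exp(-x))` — bounded, monotone and
order-preserving, the standard choice when PSSMs feed a neural network —
and accepts any other transform as an argument.

The network input is fixed at 1000 x 20. Shorter profiles are zero-padded
at the end; longer ones keep the first 500 and last 500 rows. Sorting
signals (signal peptides, terminal targeting motifs) concentrate at the
N- and C-termini, so the 500 + 500 splice preserves the sequence segments
that carry most of the label-relevant information.

## Architecture

The network has eight parallel **lanes**, one per convolution kernel size
(1, 3, 5, 9, 15, 21, 27, 33), so that motifs are detected at eight length
scales simultaneously. Each lane applies:

1. **Conv**: 10 one-dimensional kernels, stride 1, ReLU, with dropout
   (rate 0.5) during training. Padding is zero/'same', so the positional
   grid keeps the input length — required for the per-position capsule grid
   below.
2. **PrimaryCaps**: 8 channels of convolutional capsules; each capsule is a
   16-dimensional vector produced by size-1 convolutional units and passed
   through the squashing nonlinearity. With the default stride of 1 this
   yields one capsule per sequence position and channel (8000 per lane at
   full input length). The stride is configurable (`primary_stride`) for
   the variant geometry in which positions are subsampled.
3. **HiddenCaps**: eight 16-dimensional capsules per lane. Every primary
   capsule predicts every hidden capsule through an affine map
   `W[c, j]` shared across the positional grid within a channel; the
   predictions are combined by dynamic routing (below).

Hidden capsules from all lanes are concatenated, passed through a 128-unit
dense ReLU layer and a 2-class softmax. Class index 2 ("secretory") is the
positive class.

### The squashing nonlinearity

`squash()` rescales a capsule vector's length into a probability-like range
while preserving its direction. Two variants are provided:

* `"sabour"` (default): `v = (|s|^2 / (1 + |s|^2)) * s/|s|`, whose output
  norm grows monotonically from 0 toward 1;
* `"as_printed"`: `v = (|s| / (1 + |s|^2)) * s/|s|`, whose output norm
  peaks at 0.5 and is non-monotone in `|s|`.

The first is the default because the intended semantics of a capsule —
its length encodes presence probability, approaching 1 for strong inputs —
require monotone scaling onto [0, 1); the second variant contradicts that
semantics but is kept selectable for faithfulness to architectures
described with that algebraic form. Both coincide at `|s| = 1` (output
norm 0.5), which the tests pin down analytically. A numerical epsilon of
1e-8 guards the division at `|s| = 0`; the zero vector maps to itself.

### Dynamic routing

Routing assigns each primary capsule's prediction to hidden capsules by
iterated agreement:

1. logits `b[i, j]` start at 0;
2. couplings `c[i, ·] = softmax(b[i, ·])` over the hidden capsules, so each
   input capsule distributes a unit of assignment;
3. `s[j] = sum_i c[i, j] * u_hat[j|i]`, `v[j] = squash(s[j])`;
4. `b[i, j] += u_hat[j|i] . v[j]` — skipped after the final iteration.

Five iterations are the default. The invariants — couplings nonnegative
and summing to 1 for every input capsule at every iteration, permutation
equivariance in the input index — are asserted in the test suite against a
straight-line loop implementation.

**Gradient treatment.** During training the coupling coefficients are
treated as constants of the forward pass (gradients flow through the final
weighted sum but not through the routing iterations that produced the
couplings). This "straight-through" treatment is common practice in
capsule-network implementations: the routing iterations are an inference
procedure, not parameters. It is exact when `routing_iterations = 1`
(couplings are then the constant uniform distribution), which is how the
backward pass is verified against numerical gradients; for more iterations
it is a standard approximation that leaves the descent direction intact in
practice (the scaled-down learnability results below are obtained with it).

The routing inner loops are implemented in C++ (RcppArmadillo), blocked one
sample at a time so a sample's prediction vectors stay cache-resident
across all iterations; correctness is pinned to the R loop oracle at 1e-10.

## Training protocol

* **Optimizer**: Adam with learning rate 0.001, first-moment decay 0.9,
  second-moment decay 0.999.
* **Loss**: cross-entropy plus an L2 penalty (default coefficient 1e-4) on
  weight matrices (not biases).
* **Dropout** after the first convolution of each lane only (rate 0.5).
* **Early stopping** monitors validation cross-entropy on a stratified
  held-out fraction of the bag (default 10%); training halts when it fails
  to improve for `early_stop_patience` epochs (default 10) and the best
  weights are restored.
* **Unstated knobs** exposed with conventional defaults: batch size 32,
  epoch budget 100.

**Bagging for class imbalance.** `make_bags()` draws `T` balanced subsets:
every bag contains all positives plus `n` negatives sampled without
replacement, independently per bag (defaults `T = 10`, `n = 350`, matching
a 350-positive training set). One member is trained per bag and
`ensemble_predict()` averages the member softmax outputs. Positives are
not resampled: with 350 positives each bag is exactly the 350 + 350
balanced design. `kfold_split()` provides the stratified 10-fold harness.

A single user seed fans out deterministically to bag composition and member
training (`(seed * 10007 + 7919 * index) mod 2147483563`), so the whole
pipeline is bit-reproducible on a fixed platform.

## Evaluation

`classification_metrics()` computes accuracy, sensitivity, specificity,
precision, F-score and MCC from a confusion table; any metric with a zero
denominator is reported as 0 and flagged rather than propagating NaN, so
aggregation across bags stays stable. The decision rule is
`score >= threshold`, which makes the all-positive boundary reachable.
Candidate thresholds are the midpoints between adjacent unique scores plus
sentinels below and above every score — a finite, complete sweep.
`select_threshold_max_mcc()` picks the candidate with maximal MCC,
breaking ties toward the smallest threshold; the test suite checks it
against an exhaustive scan. ROC/AUC use trapezoidal integration over the
same sweep (equal scores grouped), which equals the Mann–Whitney
pair-counting statistic; `paired_ttest()` wraps the two-sided paired t-test
for comparing metrics across bagging iterations (sidedness is a
convention choice; two-sided is the conservative default).

## Ranking and enrichment

Proteome-wide predictions are ranked by the signed confidence
`S = 2 (argmax(p) - 0.5) max(p)` in [-1, 1]: positive iff the predicted
class is secretory, with magnitude equal to the winning probability. At
the exact tie `p = (0.5, 0.5)` the first maximum (the negative class) wins,
giving `S = -0.5`; ties are flagged in the output. Ranking ties break
lexicographically by ID for determinism.

A ranked list is validated against a known marker set by counting the
overlap `k` between the top `n` proteins and the `K` markers in a
population of `N`, and evaluating hypergeometric probabilities in log
space (log binomial coefficients; populations of tens of thousands
overflow direct factorials). Two quantities are reported side by side:

* `hypergeom_pmf()` — the point probability `P(X = k)`, the quantity
  conventionally quoted in published ranking-validation tables of this
  kind; and
* `hypergeom_tail()` — the upper tail `P(X >= k)`, the statistically
  standard enrichment p-value ("at least k of the markers in the top n").

The tail is never smaller than the point probability; both are exercised
against exhaustive enumeration and against R's `dhyper`/`phyper` in the
tests. Marker IDs absent from the ranked population are dropped with a
warning — they can contribute to neither `K` nor `k`.

## Synthetic data: what it emulates, what it does not

`generate_synthetic()` produces labeled datasets whose statistical
structure mirrors what the classifier relies on:

* positives carry a terminal sorting-signal-like motif (default 12
  residues, N-terminal) with per-position substitution noise (default
  0.1), emulating degenerate biological motifs;
* negatives are drawn from families with family-specific composition
  biases — mirroring how negative sets are assembled from protein families
  disjoint from the positives — and are guaranteed motif-free;
* each sequence gets a simulated profile: per-position Dirichlet draws
  (concentration 50) mixing 80% mass on the true residue with 20%
  background, emulating a conservation profile without running any
  profile search.

`sample_negative_families()` reimplements the family-sampling rule used
for negative-set construction (keep families with at least 10 members,
draw 3 per family), and `redundancy_filter()` is a deliberately simple
stand-in for sequence-identity clustering: greedy longest-first clustering
on a shared-3-mer containment estimate with a 30% threshold. It removes
near-duplicates in fixtures; it is not an alignment-based identity tool.

What the generator does **not** emulate: real evolutionary profiles (its
profiles are conditionally independent across positions), domain
architecture, homology between the two classes, length/composition biases
of real secretory proteins. Consequently, passing the scaled-down
learnability test demonstrates that the architecture, training loop and
ensemble machinery can extract a terminal motif signal end to end — it
does not certify performance on real proteome data, which depends on real
profile searches and the curated positive/negative sets.

## Problem sizes used by the test suite

The default generator scale is 100 positives / 500 negatives with sequence
lengths 50–300 and a test-time input length of 100. The learnability check
trains a two-lane ensemble with kernel sizes 9 and 15 — receptive fields
bracketing the 12-residue implanted motif — with `T = 3` bags, batch size
16 (so the 20-epoch budget still provides a few hundred optimizer steps on
a 200-sample bag), early-stopping patience 5, and evaluates ROC-AUC on an
independently generated 50 + 50 held-out set, taking the median over three
training seeds. Oracle-equivalence checks run on instances of at most 5
positions and 2 lanes, where brute-force loop implementations are exact
and fast.

## Numerical choices and degenerate inputs

* epsilon 1e-8 in squash and log-loss guards; Glorot-uniform
  initialization everywhere.
* zero-denominator metrics: flagged zeros (see above).
* `s_value` tie: argmax returns the first maximum; flagged.
* empty families, all-small families, and marker IDs outside the
  population produce warnings and well-defined empty results, not errors;
  genuinely contradictory inputs (duplicate IDs, single-class training
  bags, bag sizes exceeding the negative pool) raise errors.

## Known limitations

* Training at the full deployed geometry (eight lanes, input length 1000)
  is supported but CPU-expensive; the package is tuned for the scaled
  geometries above on desktop hardware.
* The coupling-coefficient gradient approximation (see above) means
  full-geometry gradients differ slightly from an exactly unrolled
  routing; with the default five iterations this is a standard trade-off.
* `redundancy_filter()` is a containment heuristic, not an identity
  clustering tool.
* The profile normalization used by external profile pipelines is not
  publicly specified; the logistic default is a documented stand-in, and
  profiles produced by other normalizations can be supplied directly.
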