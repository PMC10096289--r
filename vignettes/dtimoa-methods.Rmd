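---
title: "Methods: mode-of-action DTI prediction from perturbational consensus signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mode-of-action DTI prediction from perturbational consensus signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtimoa)
```

## The problem

Most computational drug–target interaction (DTI) predictors answer only
"does compound *c* bind target *t*?". For mechanism-of-action work the more
useful question carries a sign: does the compound *activate* or *inhibit*
the target? `dtimoa` implements a pipeline that predicts signed
(activatory/inhibitory) DTIs by pairing two information sources:

* **compound structure**, embedded as the sum of learned vectors of its
  Morgan substructures (the mol2vec scheme); and
* **target state**, represented by the transcriptome response to a genetic
  perturbation of the target gene — cDNA overexpression signatures stand in
  for the *activated* target, shRNA knockdown signatures for the *inhibited*
  one.

A classifier is then trained on the concatenation
`compound vector (d) ⊕ target vector (G)` with known signed interactions as
positives. At production scale the target space is the 978-gene landmark
panel of the L1000 assay (`G = 978`) and the compound embedding is 300-d;
everything in this package is dimension-agnostic and the bundled synthetic
study runs at `G = 50`, `d = 16`.

## Consensus signatures (correlation-weighted averaging)

A target gene is typically perturbed many times — in several cell lines,
at several doses and times. The consensus vector for one gene and mode is
built by MODZ-style correlation weighting. For replicate signatures
$x_1, \dots, x_n$ the pairwise Spearman matrix $R$ (average ranks on ties)
gives weights proportional to the row sums of $R - I$, normalised to sum to
one, and the consensus is $x_{Agg} = \sum_t w_t x_t$. Replicates that agree
with the rest of the set get more weight; outliers get less.

Numerical choices the formula itself does not fix:

* **Correlation floor.** Row sums of $R - I$ can be zero or negative when
  replicates anti-correlate; off-diagonal entries are floored at `floor`
  (default `+0.01`) before the row sums, so all weights are strictly
  positive and the consensus stays inside the convex hull of its inputs.
  The floor is configurable in every entry point.
* **Degenerate sizes.** $n = 1$ returns the input with weight 1; $n = 2$
  is forced to weights $(1/2, 1/2)$ because both row sums equal the single
  mutual correlation. Both are explicit fast paths, as is the bit-exact
  return of the replicate when all inputs are identical.
* **Constant replicates.** A signature with zero rank variance has its
  pairwise correlations defined as 0 (then floored), so it cannot poison
  the weight vector.

**Two-stage aggregation.** Replicates are first collapsed *within* each
cell line (over dose/time conditions), and the per-cell-line consensus
vectors are then combined *across* cell lines. This staging stops a cell
line with many replicates from dominating the consensus: with ten noisy
replicates in cell line A and one in cell line B, single-stage pooling sits
near A's centroid while the two-stage result stays near the midpoint. The
single-stage pool is available (`single_stage = TRUE`) as a diagnostic
only.

## Extending the target space over a PPI network

Many druggable targets lack perturbational signatures. Their vectors are
*inferred* as the correlation-weighted average of the measured vectors of
their direct neighbours in a high-confidence protein–protein interaction
network (STRING combined score strictly above 900 on the 0–1000 scale; a
unit 0–1 scale is accepted with explicit declaration). Design rules:

* one hop only — no propagation or iteration;
* a gene needs at least `min_neighbors = 3` covered neighbours, otherwise
  it is not inferable (returned as absent);
* a gene's own measured vector is always excluded from its neighbour set,
  so measured-versus-inferred validation pairs are computable;
* a store lookup prefers measured over inferred when both exist.

`inference_validation()` quantifies whether inference tracks the underlying
biology: Spearman correlations between inferred and measured vectors of
the *same* gene should stochastically dominate those of *mismatched* gene
pairs (one-sided Wilcoxon rank-sum). On the synthetic planted
neighbourhoods this separation is large (median within ≈ 0.96 versus ≈ 0
between, p < 1e-10 at 30 targets).

## Compound featurization

`mol_sentence()` decomposes a molecule into Morgan environment identifier
tokens — per heavy atom, one identifier per radius (default radii {0, 1},
the mol2vec reference scheme). Identifiers are 32-bit hashes of iteratively
refined invariants (element, heavy degree, bond-order sum at radius 0; the
sorted neighbour environment list at higher radii), computed on the
OpenBabel-canonicalised structure, so they are deterministic and invariant
across equivalent SMILES spellings. Salts and mixtures keep the largest
covalent fragment. `embed_compound()` sums the embedding-table vectors of
the tokens, duplicates counted with multiplicity; unknown tokens are
skipped by default (a `zero` policy is available) and their rate is
reported per compound. Binary Morgan (hashed, 2048 bits, radius 2) and
MACCS (166 keys, via OpenBabel) fingerprints are provided for embedding
comparisons.

The embedding table itself is an input artifact: training the word2vec
model is upstream of this package, and any token→vector TSV can be
supplied. Synthetic studies use random tables, which exercises every
contract (summation, dimension, unknown handling) without the published
table.

## Datasets, tiers and negative sampling

Curated interaction tables are mapped to modes case-insensitively
({activator, agonist} → activatory; {inhibitor, antagonist} → inhibitory);
all other terms are dropped and counted. Three dataset tiers mirror the
provenance of the target vector: **original** (measured only),
**additional** (inferred only), **integrated** (either, measured
preferred). Feature rows are always compound-first concatenations.

Because no gold-standard negative set exists, negatives are drawn uniformly
without replacement from the compound × target grid spanned by the positive
set of the same mode, minus those positives. Cross-mode positives are *not*
excluded (an activatory positive may be sampled as an inhibitory negative).
Training folds use 1:1 negatives; test folds use the configured ratio (1 or
10 — the 1:10 setting mimics screening prevalence, where positives are ~9%
of the test set). Every fold draws its own negatives with a seed derived
from the master seed; negatives may recur across folds, positives never
cross folds within a repeat.

## Classifiers

The selected model is a **cascade deep forest**: levels of probability
forests, half random forests and half extremely randomized trees (via
`ranger`), where each level after the first sees the raw features plus the
previous level's per-forest out-of-fold class probabilities
(`input_dim + 2 × n_estimators_per_level` columns). Level depth is chosen
by the data: training stops when a new level fails to improve the
out-of-fold metric by more than `stop_tolerance` (default `1e-4`, capped at
`max_levels = 20`), and the best-scoring prefix is kept. AUPR is the
default selection metric — the right choice under class imbalance — with
AUROC and accuracy available. All per-forest/per-fold seeds derive from
one config seed, so fits are exactly reproducible.

Defaults are desk-scale: 4 estimators × 100 trees per level, which keeps
the synthetic benchmark (1,000 rows × 66 features) to a few seconds per
fit; the production-scale optimum reported for this task (8 estimators ×
500 trees) is reachable through `cascade_config()`. Baselines share the
`predict_scores()` contract: logistic regression (z-scaled features, fitted
on training data only; aliased columns drop out of the score), a single
probability random forest, and an MLP. The MLP is a single-hidden-layer
`nnet` perceptron (default 32 units, weight decay 1e-3): R's `nnet` does
not stack hidden layers, and the MLP is a comparison baseline rather than
the selected model, so a deeper architecture was not worth a heavier
dependency. `grid_search()` implements greedy coordinate descent over a
named hyperparameter grid (one axis at a time, ties to the first-listed
value, CV-AUPR scoring), evaluating at most the sum — not the product — of
the axis lengths.

## Evaluation and screening utilities

* **AUROC** is the normalised Mann–Whitney U statistic (midranks on ties);
  **AUPR** is the step integral of the precision–recall curve over distinct
  thresholds. Both are validated in the tests against exhaustive
  pair-counting and against an independent implementation.
* **EFx%** (enrichment factor) is precision at the operating point divided
  by positive prevalence, with the operating point chosen as the largest
  threshold whose FPR does not exceed x% (the conservative side of the
  discrete ROC; a nearest-FPR policy is available). When no threshold with
  positive calls reaches the level — a constant scorer is the canonical
  case — the least-FPR operating point with positive calls is used, which
  prices a no-information scorer at exactly EF = 1 (chance).
* **Reference ranking**: a query pair's score is ranked within the score
  distribution over a reference drug library for the same target (e.g.
  2,500 approved drugs), counting strictly greater scores (optimistic on
  ties, the tie rule is recorded in the output); top percentage is
  `100 × rank / reference size`. **Rediscovery** uses a strict `> 0.5`
  threshold; a score exactly at the threshold is not a call.
* **`cross_validate()`** runs the repeated k-fold protocol (default 5 × 5
  at production scale; the test suite and acceptance script use 5 × 2) and
  reports per-fold AUROC/AUPR/EF with means and SDs. Identical master seeds
  give byte-identical results.

## What the synthetic study emulates — and what it does not

`synthetic_config()` defines the desk-scale study every test runs on:

| parameter | default | role |
|---|---|---|
| `G` | 50 | gene panel size (978 at production scale) |
| `n_targets` | 30 | perturbed genes |
| `cells_per_target` × `conditions_per_cell` | 3 × 3 | replicate grid |
| `noise_sd` | 0.5 | replicate/label noise SD (z-score units) |
| `ppi_degree` | 4 | planted neighbours per target (first two targets get 2) |
| `d`, `n_compounds` | 16, 200 | embedding dim, library size |
| `n_positives` | 500 | planted positives on the 6,000-pair grid |
| `signal_strength` | 1 | scale of the planted signal (0 = pure noise) |

Truths are i.i.d. `N(0, I_G)`; replicates add Gaussian noise; PPI
neighbours carry noisy copies of their target's truth plus decoy edges the
confidence threshold must drop. Interaction labels come from a rank-one
latent surface: with standardised projections `p = a'c` and `q = b't`, the
propensity is `plogis(signal_strength · scale(p + q + 2pq) + ε)` and the
top `n_positives` pairs are positive. The main effects guarantee the
signal is recoverable by a linear classifier — a transparent floor for any
stronger model — while the doubled product term is a genuine
compound–target interaction that a linear model on concatenated features
cannot represent but tree ensembles can. A pure bilinear plant was
rejected by design: `c'Wt` is uncorrelated with the concatenated features,
so every classifier in this feature space would sit at chance and the
benchmark would measure nothing.

What passing on this generator shows: the aggregation, inference,
featurization, sampling and evaluation machinery is numerically correct,
and the cascade recovers a planted learnable signal at least as well as a
linear baseline (out-of-fold AUROC ≈ 0.89–0.92 at the defaults). What it
does not show: performance on real L1000/STRING/TTD data, which carries
technology noise (beadset effects, dose–response shapes), correlated gene
panels, and biased curation that the Gaussian model deliberately omits.

## Degenerate inputs and tie-breaks (summary)

* Spearman on a constant vector → 0; length < 2 → error.
* Aggregating zero signatures → error; one → identity.
* Inference below `min_neighbors` covered neighbours → absent, never error.
* Negative sampling beyond universe capacity → capacity error stating the
  shortfall.
* Greedy search ties → first-listed value; ranking ties → optimistic rank;
  rediscovery at exactly the threshold → not called.
* All floating-point test comparisons at 1e-9 absolute unless a tighter
  bound is stated (the aggregation oracle is checked at 1e-10).

## Problem sizes used by the test suite and acceptance script

The suite runs the generator defaults above: 200 random oracle instances,
50-target aggregation studies over 3 seeds, a 30-target inference graph,
and 3 benchmark fits of 1,000 rows × 66 features for the cascade/logit
comparison, plus a 5-fold × 2-repeat CV pair at both test ratios. These
sizes run the whole pipeline in about a minute on one CPU while leaving
every statistical conclusion stable across seeds.

## Known limitations

* Morgan identifiers are package-native hashes: stable, canonical and
  collision-resistant at 32 bits, but not numerically interchangeable with
  RDKit's identifiers — an embedding table trained against RDKit tokens
  must be re-keyed before use.
* Atom invariants omit formal charge and isotope labels; two molecules
  differing only in those may collide at radius 0.
* The MLP baseline has one hidden layer (see above).
* GCT support is the 1.2/1.3 text dialect; binary GCTX/HDF5 is out of
  scope.
* `inference_validation()` caps between-gene pairs at `max_between`
  (default 5,000), enumerated deterministically, to bound runtime on large
  stores.
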