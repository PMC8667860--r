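---
title: "Profile-based DNA-binding protein prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based DNA-binding protein prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmDBP)
```

## The problem and the data model

DNA-binding proteins (DBPs) carry domains that recognise DNA either
specifically (transcription factors) or non-specifically (packaging and
repair machinery). Predicting the binding property from sequence alone
is a classic binary classification task, and the most informative
sequence representation is evolutionary: the position-specific scoring
matrix (PSSM) produced by iterative PSI-BLAST search. A PSSM is an
L × 20 matrix of integer log-odds scores; entry (i, j) scores the
substitution of position i by amino acid j, positive where a mutation
is well tolerated in the protein family and negative where the position
is conserved.

`pssmDBP` consumes pre-computed ASCII PSSM files (the
`-out_ascii_pssm` dialect; profiles are conventionally built with three
PSI-BLAST iterations at E-value 0.001 against a non-redundant database).
Only the 20 log-odds columns are modelled; the weighted-percentage block
is ignored on read and zero-filled on write, so write/parse round-trips
are exact on the part the pipeline uses. Column order is the PSI-BLAST
native order `A R N D C Q E G H I L K M F P S T V W Y`, fixed once as
`AA_ORDER` and shared by every downstream index computation. Rows whose
residue is `X` are kept — their scores are defined — but contribute to
no residue group in the composition descriptor.

## The three descriptor blocks

Raw integer log-odds are used directly; no squashing transform is
applied by default because each descriptor is defined on `p[i, j]`
itself. A logistic option (`sigmoid = TRUE`, mapping scores through
`1/(1 + e^{-p})`) is available for users who prefer bounded inputs.

**AADP-PSSM (420-d).** The per-column mean
`x_j = (1/L) Σ_i p[i, j]` (20 values, an evolutionary amino-acid
composition) concatenated with the dipeptide cross-products
`y_ij = (1/(L−1)) Σ_k p[k, i] p[k+1, j]` (400 values). The dipeptide
part reads consecutive *rows*, not letters, so sequence positions
holding `X` still contribute local-order information.

**PSSM-COMPOSITION (400-d).** Rows are grouped by the residue occupying
each position: `c_aj = (1/L) Σ_{i: res_i = a} p[i, j]`, a 20 × 20
matrix flattened row-major. The descriptor's defining range is
[−1, 1]; the simplest map achieving it is a per-sample min-max rescale
over the 400 entries, `v' = 2(v − min)/(max − min) − 1`, and that is
the default. Per-sample (rather than dataset-level) scaling keeps each
feature vector a pure function of its own PSSM — dataset-level scaling
would leak test-set statistics into training. All-constant vectors map
to 0. The unscaled values are available (`scale = FALSE`) and are what
the brute-force oracle tests compare against.

**RPSSM (110-d).** The 20 columns are collapsed to a 10-letter reduced
alphabet — ten is about the smallest residue alphabet that still
supports reasonable fold modelling. The default grouping is
`{FYW} {ML} {IV} {ATS} {NH} {QED} {RK} {C} {G} {P}`; it is a
constructor argument (`reduction_scheme()`), not a constant, since
other groupings are defensible. Each reduced column is the *mean* of
its member columns (a sum would inflate three-member groups relative to
singletons; configurable). Over the reduced profile `p̃` the descriptor
takes the 10 per-column population variances
`D_s = (1/L) Σ_i (p̃[i, s] − mean_s)²` and the 100 consecutive-position
terms `D_st = (1/(L−1)) Σ_i (p̃[i, s] − p̃[i+1, t])²/2`. The dipeptide
term is sometimes written with a `+` inside the square, but it is
described as measuring the *difference* between consecutive reduced
scores, and only the difference form makes the term a local-change
statistic (and keeps all 110 entries non-negative); the difference form
is therefore the default, with the sum form available as
`rpssm(form = "sum")` for comparison.

Fusion concatenates AADP-PSSM | PSSM-COMPOSITION | RPSSM in that fixed
order: 420 + 400 + 110 = 930 dimensions, regardless of the order parts
are supplied in. Feature names (`AAC.A`, `DPC.A.R`, `COMP.C.W`,
`RPSSM.DD.FYW.ML`) make the flattening order auditable.

Degenerate inputs fail loudly with typed conditions: an empty matrix,
or L < 2 for the dipeptide-bearing descriptors, raises a degenerate
input error rather than returning NaNs.

## MRMD feature ranking and prefix selection

Relevance of feature i is `maxMR_i = |Pearson(f_i, C)|` against the 0/1
label vector; a zero-variance feature is assigned relevance 0 rather
than NaN. Redundancy combines three pairwise measures of feature i
against every other feature: Euclidean distance, cosine similarity and
the Tanimoto coefficient, each averaged over the M − 1 partners, then
`maxMD_i = (ED_i + COS_i + TC_i)/3`.

Two numerical choices matter here:

* **ED normalisation.** ED is unbounded while COS and TC lie in
  [−1, 1]; an unnormalised mean is dominated by ED's scale. The mean
  Euclidean component is therefore min-max normalised across features
  to [0, 1] before entering `maxMD` (disable with
  `normalize_ed = FALSE`).
* **Similarities in a "distance" score.** As defined, `maxMD` mixes one
  distance with two *similarities*, so a feature highly similar to the
  rest is not always penalised — in particular, duplicating a feature
  lowers its mean Euclidean distance but raises its mean cosine. The
  definition is kept as the default for fidelity; the coherent
  all-distances reading is available as `similarity = "complement"`
  (which uses 1 − COS and 1 − TC), and the package's property tests
  assert the part of the monotonicity that the default form genuinely
  has (the Euclidean component never increases under duplication).

The combined score is `w·maxMR + (1 − w)·maxMD` with `w = 0.5` — equal
weighting of the two criteria, the original MRMD convention; `w` is an
argument. Ties are broken by original feature index, so rankings are
total and stable. An alternative aggregation is named after PageRank:
no canonical graph accompanies the name, so the implemented
interpretation builds a directed feature graph with an edge j → i
whenever i outranks j in any of the four constituent orderings (maxMR,
ED, COS, TC), uniform weights, damping 0.85, and ranks by PageRank
score. Both modes are deterministic; the score mode is the default.

Subset selection walks the ranking, adding one feature at a time, and
scores each prefix by stratified k-fold cross-validated accuracy
(folds fixed once per call by the seed, shared across prefixes); the
chosen subset is the smallest prefix attaining the maximum mean fold
accuracy. Whether the original folds were stratified is not stated
anywhere; stratification is chosen because it keeps both classes in
every training fold at the sample sizes involved. The selection-stage
forest deliberately uses modest defaults (500 trees, unlimited depth,
√M features per split) — the expensive final-model configuration is not
needed to compare prefixes — and a `k_grid` argument lets wide tables
be scanned at coarser resolution. The exact O(M²N) pairwise
computation is used throughout; at M = 930 it is a dense 930 × 930
Gram-matrix operation and takes well under a second.

## Classification and evaluation

The classifier is a random forest of 800 trees with maximum depth 50
and all features available at every split, matching a configuration
tuned for very wide PSSM feature tables. Where "no limit" and
"depth 50" are both plausible readings of that configuration, the more
specific depth bound wins as the default, and `max_depth = NULL`
restores unlimited growth. Training runs single-threaded with a fixed
seed, so models, their content hashes, and all downstream reports are
reproducible run-to-run. A sample's score is the fraction of trees
voting for the DBP class (tree votes, not probability-tree averages),
and the decision threshold is 0.5 — there is no evidence the original
threshold was tuned, and the full ROC sweep is always available.

Metrics follow the standard formulas: ACC, SN, SP as percentages and
Matthews correlation in [−1, 1], with the accuracy denominator being
the total count (one published rendering of the formula contains an
obvious typo repeating FP) and the usual MCC = 0 convention when a
denominator factor vanishes (flagged via `mcc_degenerate`). The ROC is
a descending-threshold sweep with tied scores grouped into single
steps; the trapezoid AUC then equals the Mann–Whitney concordance
probability with ties counted one half — an identity the test suite
checks against an O(n²) pairwise oracle and against pROC.

Cross-validation pools the out-of-fold predictions and computes one
report on the pooled set — pooling yields a single well-defined
confusion matrix, whereas per-fold averaging of ratio metrics does not;
per-fold accuracies (mean ± sd) are attached alongside.

## The synthetic generator

Real benchmark profiles require a PSI-BLAST run against a large
database, so the package ships a generator that emulates the *shape*
of that input: integer log-odds drawn as rounded N(0, 4²) clipped to
[−8, 12] (the band typical profile scores occupy), lengths uniform on
50–200 (typical domain-scale proteins), residues uniform over the 20
letters. Class signal is a mean shift of size `effect` applied to four
fixed columns (A, R, N, D) in positives — fixing the columns gives
ranking tests a known ground truth, since the corresponding AAC
features are provably informative. The default effect is 4, a clearly
learnable but not degenerate separation; effect 0 makes the classes
exchangeable by construction, which is what the null-calibration tests
rely on.

What the generator does *not* emulate: correlated profile columns,
conserved motifs, residue-dependent score structure, realistic length
and composition biases. Passing signal-recovery tests therefore
demonstrates that the pipeline's plumbing, ranking and learning behave
correctly on a controlled signal — not that any particular accuracy
will be achieved on real DBP benchmarks, which depend on the profile
database and search parameters.

## Problem sizes and determinism

The test suite exercises the extractors and rankers against
independently coded brute-force oracles on hundreds of random instances
(200 profiles per extractor, 250 random tables for the ranking, 500
confusion matrices, 400+ score sets), and runs the full
signal-recovery condition at 100 + 100 samples × 930 features with
10-fold CV — sizes chosen so the whole suite completes in a few
minutes on a single core while still covering every code path at
realistic dimensionality. Every stochastic step (simulation, fold
assignment, forest growth) is governed by an explicit seed, scoped so
package calls never disturb the caller's RNG stream; identical seeds
give byte-identical feature tables, rankings, reports and model hashes.

## Known limitations

* The pipeline consumes pre-computed PSSMs; it neither runs PSI-BLAST
  nor checks that profiles were built with consistent search settings,
  which materially affect descriptor values.
* MRMD's redundancy term is exact O(M²N); this is instant at M = 930
  but would need the documented sampling approximation well above
  M ≈ 2,000.
* The full prefix search refits k-fold forests for every prefix size;
  on 930 features use `k_grid` unless the extra resolution is needed.
* Binary labels only; multi-class DNA-binding subtypes are out of scope.
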