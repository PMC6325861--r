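---
title: "Methods: nine-feature scoring and classification of hypothetical proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nine-feature scoring and classification of hypothetical proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpscore)
```

# The problem

A hypothetical protein (HP) is a predicted gene product with no
experimental evidence of translation. Annotation pipelines accumulate
heterogeneous evidence about such proteins — domain matches, orthologs,
interaction partners, localization signals, structural templates,
pseudogene and non-coding RNA signatures — and the question is how to turn
that evidence into a defensible functional call. `hpscore` implements a
nine-feature binary scoring schema: each feature contributes a 0/1 score
under a fixed rule, the scores sum to a Total Reliability Score (TRS,
range 0–9), and the nine-bit vectors feed binary classifiers that separate
HPs (positive class) from known functional proteins (negative class).

# The scoring rules

Evidence arrives as one record per (protein, feature): an ordered list of
hits, each with organism, E-value, bit score, percent identity, and boolean
annotations. Three exclusion tags — `predicted`, `synthetic`,
`end_to_end_alignment` — disqualify a hit from every rule; this filter is
applied uniformly rather than only to the pseudogene rule, since the
exclusions describe unusable evidence, not a property of one feature.

* **Pseudogene (feature 7).** Score 1 iff a retained *Homo sapiens* hit
  passes the E-value cutoff and lacks an ATG start codon in all six
  reading frames. The source criterion is stated as "E-value less than
  zero", which is impossible for an E-value; we read it as `E < 1`
  (i.e. negative log10) and expose the cutoff as
  `pseudogene_evalue_cutoff` (default 1.0) so any stricter reading is one
  configuration away.
* **Homology modelling (feature 8).** Score 1 iff a retained PDB-template
  hit has percent identity *strictly* greater than
  `homology_identity_threshold` (default 30). "More than 30%" is read as a
  strict inequality; the boundary behaviour at 29.9 / 30.0 / 30.1 is
  pinned by tests.
* **Non-coding RNA (feature 9).** The top `ncrna_top_k` (default 3)
  *H. sapiens* hits are examined; when the relative bit-score spread
  `(max − min)/max` among the top `ncrna_extended_k` (default 5) such hits
  is below `ncrna_score_spread_fraction` (default 0.05) — "no considerable
  difference between scores" — the window widens to 5. Score 1 iff an
  examined hit is ncRNA-annotated.
* **Legacy features 1–6** (Pfam, orthology, protein interactions,
  bidirectional best BLAST hits, subcellular localization, functional
  linkages) come from an earlier six-point schema whose detailed criteria
  are not restated here; they are driven by a per-feature rule table with
  two rule types. `evalue` rules (features 1, 3, 6; default cutoff 1e-3,
  a conventional domain/association significance level) test the
  best-ranked retained hit; `presence` rules (features 2, 4, 5) test
  whether any retained hit exists. All cutoffs are configuration, not
  claims about the original criteria.
* **Missing evidence scores 0**: absence of evidence is treated as the
  criterion not met, which keeps the schema total and the TRS well
  defined.

Scoring is a pure function of (records, configuration): the same input
yields byte-identical matrices, and adding a qualifying hit can never
lower a score.

# The synthetic data generator

No per-protein feature matrix is published for the original 300-protein
study set, so every downstream stage is exercised on synthetic data with
the documented structure: 106 positive and 194 negative rows, per-class
Bernoulli probabilities per feature, and induced positive correlation for
the feature pairs 1&2, 5&6 and 6&8.

The default replication profile places the positive class high on the
high-impact features (Pfam, orthology, functional linkages, pseudogene,
ncRNA; p between 0.85 and 0.95) and the negative class low there (p
between 0.05 and 0.15), with the remaining features weakly informative.
These values are a design choice made once: they produce the well
separated, high-90s-accuracy regime the schema is reported to operate in,
without claiming any published number.

Correlation is induced by a value-copying mixture: for a pair (i, j, w)
the target feature j copies the realized value of the source i with
probability w (default 0.5), else draws independently. This is simple,
bounded and analytically tractable: with equal Bernoulli p on both
features the marginals are preserved exactly and the induced Pearson
correlation is w. When the pair's p values differ, the copy shifts the
target's marginal toward the source's — which is why the *validation
profile* used in the parameter-recovery checks (`validation_profile()`,
n = 2000 per class) assigns equal p within each induced pair, so empirical
frequencies are unbiased estimates of the specified probabilities. The
default profile directs the copies as (1→2), (6→5), (6→8), keeping the
strongly informative features 1, 2 and 6 at their nominal marginals. Note
the chained pairs make features 5 and 8 share a source, so their mutual
correlation is elevated (≈ w²) though below the induced pairs (≈ w).

The generator emulates only what the rules need: binary scores, class
imbalance, pairwise correlation, and evidence records that rescore to the
same matrix (E-values log-uniform within the qualifying or disqualifying
band, identities uniform within theirs). It does not simulate sequences,
alignment statistics, realistic E-value distributions, or the biological
dependence structure of real annotation databases — so green tests say the
*pipeline* is correct, not that real HP data is this easy to separate.

# Classifiers

All four families are implemented from scratch on the nine-bit vectors,
predict `"positive"`/`"negative"`, and resolve exact decision ties to the
negative (majority) class. Fits are deterministic given (data,
configuration, seed), and models serialize to JSON and reload with
bit-identical predictions over all 2⁹ inputs.

**Pocket perceptron.** Online unit-step perceptron,
w ← w + η(y − ŷ)x, with a "pocket" holding the best-training-accuracy
weights seen so far; the pocket is returned, so accuracy over the trace is
non-decreasing even on non-separable data. Defaults follow the documented
run: η = 0.2, 1000 iterations, a random length-9 weight vector (uniform on
[−1, 1]). An *iteration* is read as one example presentation, with epochs
visited in seeded-shuffled order; per-epoch updating is the other
defensible reading, and the trace makes either auditable. The length-9
weight vector implies no bias term, so the default decision hyperplane
passes through the origin and the all-zero vector is always negative.
That geometry is restrictive on imbalanced binary data whose boundary
sits near TRS ≈ 4.5: on the replication profile the best through-origin
linear separator reaches only ≈ 87–93% training accuracy. `include_bias =
TRUE` lifts the restriction, and the evaluation pipeline uses the biased
perceptron for that reason, while the bare configuration keeps the
documented parameters.

**Bernoulli naive Bayes.** Class priors are empirical; conditionals use
additive smoothing θ = (n₁ + α)/(n_c + 2α) with α = 1 by default (the
features are bits, so the Bernoulli event model is the natural choice).
With α = 0 a zero-probability conditional short-circuits the class
likelihood; the implementation uses a finite log-zero sentinel so the
prediction stays defined with no division by zero.

**Decision tree.** C4.5-style recursive partitioning by gain ratio
(information gain / split information; plain gain optionally), ties to
the lowest feature index, stopping at pure nodes, exhausted paths, or
nodes smaller than `min_leaf` (default 2). Zero-gain splits are still
taken when a usable feature exists — necessary for XOR-like interactions,
where no single feature has positive marginal gain. Confidence-factor
pruning is deliberately out of scope; on nine binary features the
unpruned tree is small and deterministic.

**SVM (SMO).** The soft-margin dual is solved by Platt-style sequential
minimal optimization: pairs of multipliers optimized analytically with
clipping to [0, C], which preserves Σαᵢyᵢ = 0 exactly; convergence is
declared after `max_passes` sweeps with no KKT violation beyond `tol`
(default 1e-3). The partner index is drawn from a seeded RNG, making the
fit reproducible. Kernels: linear, polynomial (x·y + 1)^d, RBF
exp(−γ‖x−y‖²), and the normalized polynomial (unit self-similarity). The
tests cross-check predictions against an interior-point QP solution of
the same dual on small data.

# Evaluation

The six confusion-matrix metrics follow the standard formulas; any metric
with a zero denominator is reported as `NA`, never silently zeroed. One
deliberate correction: the printed MCC formula in the source omits the
square root over the denominator product, which breaks the [−1, 1] bound;
the standard square-rooted MCC is computed by default and the unrooted
variant is available via `mcc_sqrt = FALSE` for audit.

Stratified k-fold CV assigns each class's remainder rows to the folds with
the smallest running totals, so overall fold sizes stay within one row of
n/k even under imbalance (300 rows at k = 10 give exactly 30 per fold);
folds are pairwise disjoint and complete, so no training row is ever
tested on. Both the pooled accuracy (over summed counts) and the
fold-averaged accuracy are reported, since it is ambiguous which
aggregation a given published table used. The repeated-split protocol
draws seeded stratified splits at `train_fraction` (default 0.66, the
setting attached to the documented perceptron run; 0.8 matches the other
documented protocol) and reports mean/max/min over the trace.

# Feature selection

* **CFS**: best-first forward search on the merit
  k·r̄_cf / √(k + k(k−1)·r̄_ff), stopping after 5 consecutive
  non-improving expansions (the patience is a fixed, documented choice),
  lexicographic tie-breaking, constant columns excluded with a warning.
* **PCA ranking**: principal components of the centered score matrix;
  features ranked by Σ_c |loading| × variance-fraction. The reference
  ranker operates on transformed components yet reports original feature
  indices; projecting component importance back through absolute loadings
  is our resolution of that ambiguity, and it is flagged as such.
* **Exhaustive subset search**: all 2⁹ − 1 = 511 subsets under one seeded
  plan (identical folds for every subset), ties to the smaller then
  lexicographically smaller subset — which guarantees the winner is at
  least as accurate as the full set.
* **Impact ranking**: each feature evaluated alone; competition ranking
  (tied features share the better rank, the next rank is skipped),
  matching the tied-rank style of the reference tables.

# Similarity and significance

Jaccard similarity on nine-bit profiles is M₁₁/(M₁₁+M₁₀+M₀₁); two all-zero
profiles are treated as identical (J = 1) since they are literally the
same profile — some conventions use 0, so the count of such pairs is
reported alongside. 1 − J is a metric, and the triangle inequality is
property-tested. One-way ANOVA (classical F, equal-variance) is exposed
with an explicit degenerate flag when within-group variance is zero; the
default grouping asks, within one class, whether the nine features' score
frequencies differ.

# Numerical choices and problem sizes

Tests pin boundary behaviour (identity 29.9/30/30.1), enumerate all
evidence multisets of up to three hits against straight-line truth-table
oracles, and check the metrics against a recount oracle on 1000 random
prediction vectors at 1e-12. Stochastic checks use fixed seeds: parameter
recovery at 2000 rows per class within 3 binomial standard errors;
chance-level MCC on 10⁴ balanced rows within ±0.05; triangle inequality on
10⁴ random triples of 300 profiles. The exhaustive-search check runs all
511 subsets with naive Bayes under 5-fold CV on the 300-row profile —
small enough to be exact, large enough to exercise every code path.

# Known limitations

* The six legacy rules are a generic threshold/presence engine; the
  original criteria live in prior work and are only named here, so the
  defaults are stated as decisions, not reproductions.
* The replication profile is synthetic; published accuracy tables for the
  real 300-protein set are out of scope and are never compared against.
* The unpruned tree can overfit noisier data than the binary nine-feature
  setting it is built for.
* The pocket guarantee is "best seen so far": without a bias term there
  is no guarantee of beating the majority baseline on arbitrary data,
  though it does on the study profiles.
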