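---
title: "Methods: sequence-derived descriptors and per-family classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-derived descriptors and per-family classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profam)
```

## The problem

Many proteins have no detectable sequence or structural similarity to any
protein of known function, so alignment-based annotation transfer fails for
them. profam takes the alternative route: it represents a protein purely by
sequence-derived structural and physicochemical descriptors and asks, for
each functional family (an enzyme class, a binding activity, a GO process
grouping, ...), whether a query's descriptor vector looks like the family's
members. Each family is an independent binary member/non-member model; there
is no multi-class formulation, mirroring how such family servers are built.

## Protein representation

### Amino-acid composition

The 20 residue frequencies, in fixed alphabetical order. This is the
composition "property" of the descriptor set and is kept as its own
20-dimensional block.

### CTD over three-class property groupings

For each physicochemical property, the 20 amino acids are partitioned into 3
classes and the sequence is transcribed into its class string. Three
encodings are computed per property:

* **Composition** `C_j`: fraction of residues in class *j* (3 values).
* **Transition** `T_{rs}`: number of adjacent pairs whose classes are
  `{r, s}` in either order, divided by `L - 1`, for the pairs (1,2), (1,3),
  (2,3). A length-1 sequence has zero transitions by definition.
* **Distribution** `D`: for each class, the fractional sequence positions
  (1-based position over `L`) of the first, 25%, 50%, 75% and last
  occurrence (15 values).

Each property block therefore has 3 + 3 + 15 = 21 elements; the default
configuration uses 12 grouped properties, giving 20 + 12 × 21 = 272 features.

**Distribution quantile rule.** For a class with `n` occurrences the five
occurrence indices are `(1, max(1, floor(0.25 n)), max(1, floor(0.50 n)),
max(1, floor(0.75 n)), n)`. This is the unique simple rule consistent with
the published two-letter worked example (for `n = 14`, indices 3, 7, 10
reproduce 0.27, 0.60, 0.77; for `n = 16`, index 4 reproduces 0.17), and it
is pinned by tests. An absent class yields five zeros, keeping the dimension
fixed. Note the source material prints the worked transition value once as
`15/29 = 0.52` and once as `0.51`; `15/29 = 0.517`, so 0.52 is the correct
two-decimal rounding and the implementation follows the arithmetic.

**Property tables.** The class assignments per property are not part of the
published method description, so profam ships the standard literature
groupings (the Dubchak-style tables used throughout the CTD literature for
hydrophobicity, normalized van der Waals volume, polarity, polarizability,
charge, secondary-structure propensity, solvent accessibility, and surface
tension) and three-bin tercile splits of published amino-acid index values
for the four remaining properties (residue molecular weight, water
solubility, and side-chain hydrogen-bond donor/acceptor counts). All
twelve live in an editable packaged TSV
(`inst/extdata/property_groupings.tsv`), loaded at runtime, so alternative
assignments can be substituted without touching code.

### Moreau-Broto autocorrelation

For an amino-acid index `p` (normalized to mean 0, unit population standard
deviation over the 20 values) the lag-d autocorrelation is

    AC(d) = (1 / (L - d)) * sum_{i=1..L-d} p(i) p(i+d),  d = 1..max_lag.

The exact normalization is not printed in the method description; this
averaged normalized form is the standard one in the descriptor literature.
Defaults: `max_lag = 30`, scales = Kyte-Doolittle hydrophobicity and residue
molecular weight; the block is off unless enabled in the configuration,
matching the default 272-dimension layout.

### Pseudo-amino-acid composition

Chou's classic formulation: components 1..20 are `f_a / (1 + w Σθ)` and
components 20+k are `w θ_k / (1 + w Σθ)`, where `θ_k` averages, over
positions and over the supplied scales, the squared difference of normalized
index values between residues `i` and `i + k`. Defaults are Chou's customary
`λ = 10`, `w = 0.05` over hydrophobicity, hydrophilicity and side-chain
mass; no parameter values are given in the source description, so these are
configurable. `λ = 0` collapses to plain composition, which the tests pin.

## Classifiers

All three backends first apply min-max scaling fitted on training data only
(constant features map to 0). Scaling is unstated in the method description,
but the Euclidean-distance backends and the Gaussian kernel are meaningless
across blocks of different magnitudes without it.

### Gaussian-kernel soft-margin SVM

The max-margin hyperplane with kernel
`K(xi, xj) = exp(-||xj - xi||^2 / (2 σ^2))` is found by solving the usual
dual with box constraints `0 ≤ α_i ≤ C_i`, where `C_i = cost × weight_pos`
for members and `cost × weight_neg` for non-members — the per-class cost
pair that the imbalance discussion calls for. No SVM library is available in
the target environment, so the dual is solved by a sequential minimal
optimization (SMO) routine in C++ with maximal-violating-pair working-set
selection (stopping tolerance 1e-3 on the KKT violation). A query is a
member iff the decision value `f(x) = Σ α_i y_i K(x_i, x) + b` is strictly
positive; `f(x) = 0` breaks to non-member, the conservative choice under the
real-world imbalance where non-members dominate.

### Platt probability calibration

Member probabilities for the SVM are `P(y=1|f) = 1 / (1 + exp(A f + B))`.
`(A, B)` minimize the negative log-likelihood with Platt's smoothed targets
`(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` (the regularization) on *out-of-fold*
decision values from a stratified 3-fold cross-validation of the model's own
training set, via Newton iteration with backtracking. Degenerate input (all
decision values equal) falls back to the class-prior constant with a
warning. kNN and PNN do not get Platt calibration; they report native
normalized scores (see below), since the sigmoid is defined on an SVM-style
decision value.

### k-nearest-neighbour

Euclidean distance in the scaled space, majority vote among the k nearest
training vectors. k is odd by default to avoid vote ties; even k is allowed
and an exact tie breaks to non-member. The score is the member-vote
fraction; because the prediction contract requires probabilities strictly
inside (0, 1), the reported probability is the Laplace-smoothed fraction
`(votes + 1)/(k + 2)` (rule of succession), which is monotone in the vote.

### Probabilistic neural network

Class-conditional densities are the Parzen estimator exactly as
conventionally printed for this classifier,

    g(x) = (1/n) Σ_i exp( - Σ_j ((x_j - x_ij) / σ_j)^2 ),

without the Gaussian ½ factor or normalizing constant — both cancel in the
two-class Bayes rule when the smoothing is shared. A query is a member iff
`h_pos c_pos g_pos(x) > h_neg c_neg g_neg(x)` with priors `h` defaulting to
training-class frequencies and unit costs `c`; ties (including total
underflow of both densities) break to non-member. Densities are evaluated in
log space with log-sum-exp, so the σ → 0 limit degrades gracefully into
1-nearest-neighbour behaviour (a property the acceptance tests exercise at
σ = 1e-3). `σ_j` supports per-feature smoothing; the default is a single
shared σ.

## Dataset construction and the staged protocol

Positives of a family are grouped by protein name (same name, different
species fall into one group) and dealt round-robin into training, testing
and independent partitions after a seeded within-group shuffle. The
published procedure says members are "iteratively selected"; the iteration
order is not defined there, so profam deals with a cycle pointer
(train → test → independent) that starts at train and is *carried across
groups* — within any group the partition sizes differ by at most one, and
collections dominated by singleton groups still populate all three
partitions, which a per-group reset would not guarantee.

Negatives come from domain (Pfam-style) families: any domain family
containing at least one positive is excluded, and from each remaining family
up to 3 representatives are sampled uniformly without replacement (seeded)
and dealt one per partition. "Representative" is not operationalized in the
source procedure; uniform sampling is the simplest faithful reading.
Finally, duplicated proteins — identical residue strings, regardless of id —
are removed within and across partitions, keeping the copy in the
highest-priority partition (train > test > independent) so that evaluation
sets stay uncontaminated while training signal is preserved.

The protocol then (1) tunes hyperparameters on train, scored on test;
(2) retrains on train ∪ test with the chosen setting; (3) evaluates that
model on the independent partition, producing the reported TP/TN/FP/FN and
SE/SP/PR; (4) retrains a final model on all three partitions with the same
setting. The tuning criterion is balanced accuracy `(SE + SP)/2` — the
source optimizes an unstated criterion, and balanced accuracy respects its
explicit concern with imbalanced families. Grid ties break to the first
setting in grid order, so tuning is deterministic. Undefined metric ratios
(zero denominators) are reported as `NA`, never coerced to 0.

PR is implemented as `TP / (TP + FP)` (standard precision). The printed
equation block in the source says `TP / (TP + FN)` — which would duplicate
SE — while its table caption defines `TP / (TP + FP)`; the equation is read
as a typo.

## The synthetic stated world

The generator draws each residue by sampling a class of one anchor property
(hydrophobicity by default) from the profile's probability triple — or
uniformly over the 20 amino acids with probability `noise` — then uniformly
within that class. The default benchmark is one member family biased
(0.8, 0.1, 0.1) and four background families biased toward the other
classes, `n_pos = 60`, `n_neg = 300`, noise 0.1, lengths uniform on 60–120
residues, background domain families of 3 (so every negative domain family
contributes one protein per partition, as in the published sampling rule).
These values are the package's fixed stated world for the seeded acceptance
benchmarks; the 1:50 imbalance scenario (12 positives, 600 negatives) probes
the qualitative SP ≥ SE pattern reported for real imbalanced families.

What a green benchmark establishes: the full pipeline — descriptors, split
construction, tuning, calibration, evaluation — recovers a family whose
members share a strong composition bias. What it does not establish:
performance on real UniProt-scale families, whose signal involves
order-dependent and long-range features, homology structure, and far weaker
class separation. The generator has no indels, no phylogeny, no domain
architecture; it is a correctness instrument, not a realism instrument.

## Numerical choices and degenerate inputs

* SMO: stopping tolerance 1e-3, iteration cap 200,000 (a warning is raised
  if hit); support vectors thresholded at α > 1e-8; the bias is averaged
  over free support vectors, falling back to the violation midpoint.
* Comparisons with the published worked example round to 2 decimals because
  that is the printed precision; no half-way rounding cases arise there.
* Length-1 sequences: transitions are all zeros; distribution still defined.
* Sequences shorter than an enabled block's requirement (`max_lag + 1` for
  autocorrelation, `λ + 1` for PseAAC) raise an error naming the block.
* Non-canonical residues (B/Z/X/U/O, stops, gaps): dropped with a message by
  default, rejected under the strict policy; how the original server handled
  them is unrecorded, so the default keeps real-world inputs usable while
  preserving the 20-letter descriptor definitions.
* PNN probabilities are clamped to `[1e-12, 1 - 1e-12]`; kNN probabilities
  are Laplace-smoothed — both so reported probabilities are strictly inside
  (0, 1).
* Cross-method ranking in the CLI is refused rather than fudged: Platt
  probabilities and vote/posterior scores are not comparable across
  backends.

## Known limitations

* The 12 shipped groupings are literature defaults, not the (unpublished)
  tables of the original server; results depend on them, which is why they
  are data, not code.
* The SMO solver is exact for the small-to-moderate problems this package
  targets (thousands of training vectors); it makes no attempt at shrinking
  or caching for database-scale training.
* No BLAST post-prediction step and no web interface; the CLI `predict`
  output is the integration point for any downstream alignment tooling.
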