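---
title: "Multi-frequency multiplex analysis of brain connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-frequency multiplex analysis of brain connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfnet)
```

## The model

Functional brain networks inferred from electrophysiology are not one
network but several: each frequency band carries its own connectivity
pattern over the same cortical regions. `mfnet` represents a subject as a
multiplex network — M binary adjacency layers $A^{[\lambda]}$ over n
shared nodes, with inter-layer links only between a node and its own
replicas (identity coupling, never stored explicitly). The central
statistic is the per-node evenness of connectivity across layers. With
$o_i = \sum_\lambda k_i^{[\lambda]}$ the overlapping degree and
$NLP_i^{[\lambda]} = k_i^{[\lambda]} / o_i$ the node-degree layer
proportion, the multi-participation coefficient is

$$MPC_i = \frac{M}{M-1}\Big[1 - \sum_\lambda \big(NLP_i^{[\lambda]}\big)^2\Big],$$

normalized so that a node with equal degree in all M layers scores 1 and
a node confined to one layer scores 0. A node disconnected in *every*
layer is assigned $MPC_i = 0$ by convention (avoiding 0/0), and global
averages divide by all n nodes, disconnected ones included. The
single-layer analogue is the participation coefficient over the modules
of a modularity partition,
$PC_i = 1 - \sum_m (k_{i,m}/k_i)^2$, with the same isolated-node
convention. The across-layer degree coefficient of variation
$CV_i = \mathrm{sd}(k_i^{[1..M]})/\mathrm{mean}(k_i^{[1..M]})$ measures
the complementary quantity (dispersion rather than balance); the sd is
the population (divide-by-M) form by default, switchable to the sample
form, because the convention is not fixed by any constraint of the
method — it is documented rather than guessed.

## From signals to layers

The spectral stage estimates magnitude-squared coherence
$|S_{xy}|^2/(S_{xx}S_{yy})$ from Welch-averaged cross-spectra: 2-second
Hann-tapered segments with 25% overlap, per-segment mean removal (the
only detrending applied — anything stronger is a preprocessing decision
that belongs upstream), zero-padding to `nfft` points. The defaults
(`window_s = 2`, `overlap_frac = 0.25`, `nfft = 2000` at 1 kHz sampling)
give 0.5 Hz resolution, on which every default band edge (e.g.
theta 4.5–7.5 Hz) falls exactly; band averaging therefore includes **both
endpoints** — a half-open rule would silently drop stated band edges.
With a 2000-sample window the 25% overlap yields a 1500-sample hop;
fractional hops are floored. The order of operations is fixed:
coherence per epoch → band average per epoch → average across epochs.
Band averaging and epoch averaging are both element-wise means, so they
commute; the fixed order exists for reproducibility of intermediate
files, not numerics (the commutation is asserted in the tests). An
imaginary-coherence variant
$|\mathrm{Im}(S_{xy}/\sqrt{S_{xx}S_{yy}})|$ is provided for sensitivity
analyses: it discards zero-phase-lag coupling, which suppresses
instantaneous field spread at the cost of true zero-lag interactions.
Magnitude-squared (not magnitude) coherence is assumed throughout; a
convention choice, flagged here because both appear in the literature.

Weighted band matrices are reduced to binary layers by retaining the
$L = \mathrm{round}(k \cdot n/2)$ strongest edges for a target mean
degree k (round-half-up; the screening grid defaults to
k ∈ {1, 3, 6, 12, 24, 48}, spanning densities ≈ 0.007–0.327 at n = 148).
Fixing the *link budget* rather than a weight cutoff makes networks of
different subjects comparable by construction. Ties at the boundary are
broken deterministically (weight descending, then row, then column
index): with coherence weights exact ties are rare, but determinism
guarantees exactly L edges and reproducible networks. Negative weights
are rejected outright — coherence is nonnegative, and ranking signed
weights by magnitude would silently change the estimand.

## Statistics

Group differences use permutation t-tests: the pooled-variance two-sample
t, a null built by exchanging group labels B = 10000 times (add-one
p-values $p = (1 + \#\{|t^*| \ge |t|\})/(B+1)$, so p is never 0 and never
below $1/(B+1)$), and a Z-score standardizing the observed t against the
permutation null's mean and sd — the permutation framework defines Z, not
a parametric formula. One implementation subtlety: the single-feature
test draws its null from the *sorted* pooled sample, which leaves the
distribution unchanged but makes the Monte-Carlo p exactly invariant
under swapping the two input groups (for balanced groups). The node-wise
version instead shares one label-permutation schedule across all nodes —
one O(B) pass of group sums serves every node, and the node-wise nulls
stay jointly exchangeable; the two designs agree up to Monte-Carlo error.

Testing is hierarchical: local (node-level) tests run only for features
whose global test is significant at α = 0.05, and local p-values are then
FDR-corrected (Benjamini–Hochberg step-up by default;
Benjamini–Yekutieli selectable for arbitrary dependence). Correlations
with cognitive scores use Spearman's R with a permutation p-value
(B = 10000 score-order permutations) for consistency with the rest of the
framework. Kruskal–Wallis (tie-corrected, χ² approximation) profiles a
node's NLP across the M bands.

The representative threshold k\* is the smallest k in the screening grid
at which *both* the single-layer (PC in the band of interest) and the
multiplex (MPC) global tests are significant. When no k qualifies — which
legitimately happens when only one analysis carries signal — the pipeline
warns and continues at a configured default (k = 12) rather than
aborting, reporting the fallback in its summary.

## Classification

Feature vectors concatenate the values of a local network feature at ROIs
ranked by group-difference p-value (ties: larger |Z| first, then node
index). The classifier is Mahalanobis distance to each class mean under
the pooled within-class covariance; when the covariance is
ill-conditioned (feature count approaching the training size) a ridge
$\lambda I$ with $\lambda = 10^{-6}\,\mathrm{tr}(S)/d$ is added
automatically, and with regularization disabled a singular covariance is
a hard error advising shrinkage. Performance comes from repeated
stratified 80/20 splits — a 5-fold-sized test set, reconciling "repeated
5-fold" with "random 80/20 split"; a classical 5-fold mode is available
by flag. Acc/Sens/Spec are averaged over iterations (default 1000; 10000
for final runs) and the ROC/AUC is computed from the pooled held-out
scores $d^2(\mathrm{HC}) - d^2(\mathrm{AD})$, so larger means more
AD-like. The feature grid search evaluates every combination of top-k PC
and top-k MPC features (excluding the empty cell). Whether ROI ranking
should be computed once on the full sample or inside each training fold
is genuinely open; both are implemented, the default is **in-fold**
(leakage-free), and the in-fold ranking uses parametric two-sample-t
p-values — running a permutation test inside every split of every grid
cell would be computationally prohibitive, and only the *ordering* of
nodes is consumed.

## The synthetic cohort: what it emulates and what it does not

The generator draws, per subject, M = 7 weighted layers from a planted
partition: edge weight $\mathrm{clip}(\mu + \mathcal N(0, \sigma_w), 0, 1)$
with $\mu = w_{in}$ inside modules and $w_{out}$ between. AD-like
subjects additionally have all weights incident to an affected node set
scaled by $(1-\delta)$ in the alpha2 layer and $(1+\delta)$ (capped at 1)
in the theta layer — a multiplicative rescaling rather than edge
rewiring, deliberately: rescaling shifts those nodes' positions in the
weight ranking so the degree imbalance *survives fixed-degree
thresholding*, which is the mechanism the analysis is designed to detect
(a frequency-specific redistribution of regional connectivity, theta up,
alpha2 down). Scores follow
$\mathrm{intercept} + \mathrm{slope}\cdot\mathrm{feature} +
\mathcal N(0, \sigma_s)$, with the feature being each subject's global
MPC at k = 12.

Default parameter choices, made once: 25 + 25 subjects (a typical
two-group electrophysiology cohort); n = 148 nodes in four near-equal
modules (a standard cortical parcellation size), with n = 40 in four
modules of 10 used throughout the tests for speed; $w_{in} = 0.6$,
$w_{out} = 0.3$, $\sigma_w = 0.1$ — clear but noisy modular contrast,
weights well inside [0,1]; $\delta = 0.3$ default effect
(tests of detection use the stated 0.5 and calibration uses 0);
slope 30, intercept 0, $\sigma_s = 2$, putting scores in a plausible
cognitive-scale range (~27 at MPC 0.9). Per-subject seeds derive from
the cohort seed by one Lehmer-generator step offset by subject index
(`split_seed`), so any subject can be regenerated in isolation.

What a green test does establish: on data whose only group difference is
a layer-concentration shift, the pipeline's global MPC test is correctly
calibrated at δ = 0 (empirical type-I rate within [0.03, 0.07] over 200
replicate cohorts) and detects δ = 0.5 essentially always, localizes it,
and classifies with high accuracy. What it does not establish: anything
about volume conduction, non-stationarity, inter-subject anatomical
variability, realistic coherence spectra, or the effect sizes of real
patient data — the generator is a statistical stand-in, not a biophysical
simulation, and real MEG effect sizes (|Z| ≈ 2–3) are far smaller than
the planted δ = 0.5 effect. The worked example's null within-group score
correlation illustrates a real limitation: within-group feature variance
under this generator is small relative to score noise, so the
score-correlation path is exercised for correctness, not for power.

## Numerical and degenerate-input choices

- Coherence needs ≥ 2 Welch segments (one segment gives coherence ≡ 1);
  shorter signals error with the required minimum named.
- Isolated nodes: $PC_i = MPC_i = CV_i = 0$; NLP rows of disconnected
  nodes are all zero (and excluded from the rows-sum-to-1 invariant).
- Zero variance in both groups: the permutation test returns p = 1,
  Z = 0 with a warning instead of dividing by zero; constant node
  features are flagged the same way.
- Modularity: randomized Louvain over node permutations, best Q of 20
  restarts (seeded). On every ≤ 10-node graph in the test suite this
  attains the exhaustively enumerated optimum; on larger graphs it is a
  heuristic, as is every practical modularity maximizer.
- Round-half-up (not banker's rounding) for the edge budget
  L = round(k·n/2), so k·n odd cases resolve predictably upward.
- All on-disk matrices are written at 6 decimals; roundtrips are exact to
  1e-6 by construction, and readers validate symmetry, finiteness and
  shape with line-numbered errors.

## Known limitations

Single-band PC and multiplex MPC are the only centrality families
implemented; path- or walk-based multiplex measures need inter-layer
weights this representation deliberately avoids. The modularity partition
is computed per subject per layer — group-level consensus partitions are
out of scope. The Mahalanobis classifier is intentionally simple; no
hyperparameter tuning or alternative learners are provided. Source
reconstruction and artifact removal are upstream of this package: it
starts at ROI time series or at connectivity matrices.
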