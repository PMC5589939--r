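# mfnet — multi-frequency multiplex brain network analysis

`mfnet` analyzes functional brain networks that live on several frequency
bands at once. Electrophysiological recordings (MEG/EEG source
reconstructions) yield one connectivity network per canonical band —
delta (2–4 Hz), theta (4.5–7.5), alpha1 (8–10.5), alpha2 (11–13), beta1
(13.5–20), beta2 (20.5–29.5), gamma (30–45) — and treating those bands as
the layers of a **multiplex network** (same nodes in every layer, identity
inter-layer coupling) asks a question single-band analysis cannot: *how
evenly does each region distribute its connectivity across frequencies?*

The package is aimed at network-neuroscience researchers comparing a
patient group against controls (the motivating use case is Alzheimer's
disease vs healthy aging), and covers the full path from ROI time series
to group statistics and diagnostic classification:

- **Spectral estimation** — Welch PSD and magnitude-squared coherence
  `|S_xy|² / (S_xx S_yy)` (plus the imaginary-coherence variant, which is
  blind to zero-lag field spread), averaged into band matrices and across
  epochs.
- **Network construction** — each band matrix is thresholded to a fixed
  mean degree k (the `L = round(k·n/2)` strongest edges are kept and
  binarized, so every network has the same link budget), then stacked into
  a multiplex; *overlapping* (edge-count) and *aggregated* (union)
  flattenings are available for comparison.
- **Single-layer metrics** — modularity partitions (randomized Louvain,
  best of restarts, verified against exhaustive search on small graphs)
  and the participation coefficient
  `PC_i = 1 − Σ_m (k_im / k_i)²`.
- **Multiplex metrics** — the node-degree layer proportion
  `NLP_i^[λ] = k_i^[λ] / o_i` and the **multi-participation coefficient**

  `MPC_i = M/(M−1) · (1 − Σ_λ (NLP_i^[λ])²)`

  which is 1 for a perfectly balanced inter-frequency hub and 0 for a node
  confined to one band (or disconnected, by convention); also the
  across-layer degree coefficient of variation CV_i.
- **Statistics** — permutation t-tests (label exchange, permutation
  Z-scores, add-one p-values), hierarchical global→local testing with
  Benjamini–Hochberg FDR, Spearman correlations with cognitive scores
  (MMSE, total recall), Kruskal–Wallis NLP profiling across bands.
- **Classification** — Mahalanobis-distance classifier on p-value-ranked
  feature vectors, repeated stratified 80/20 cross-validation (or 5-fold),
  ROC/AUC, and a grid search over combined PC/MPC feature counts.
- **Synthetic cohorts** — a planted-partition generator with a
  group-dependent layer imbalance (AD-like subjects shift degree away from
  alpha2 toward theta on an affected node set) and scores coupled to
  network features, so the entire pipeline is testable and calibrated
  without any external data.

## Worked example

A synthetic 25+25 cohort on 40 nodes (4 modules of 10) with a strong
planted imbalance (`delta = 0.5`) on the first module:

```r
library(mfnet)
spec <- cohort_spec(n_hc = 25, n_ad = 25, n_nodes = 40,
                    module_sizes = rep(10, 4), delta = 0.5,
                    affected_nodes = 1:10, seed = 42)
cohort <- generate_cohort(spec)
config <- pipeline_config(k_grid = c(6, 12, 24), B = 1000, cv_iter = 200,
                          max_k_each = 3, restarts = 10, seed = 42)
res <- run_pipeline(cohort, config)
```

Output (abridged, exactly as printed):

```
stage=screen k=6 p_pc=0.2398 p_mpc=0.000999
stage=screen k=12 p_pc=0.3556 p_mpc=0.000999
stage=screen k=24 p_pc=0.8941 p_mpc=0.000999
stage=threshold k_star=12 fallback=TRUE
global MPC: t = -43.286, Z = -42.39, p = 0.0010
MPC~TR Spearman R = -0.108, p = 0.6044
best CV cell: k_pc = 0, k_mpc = 3, Acc = 100.0%
```

Reading the numbers:

- The global **MPC deficit in the AD-like group** is detected at every
  threshold (p = 0.000999 is the smallest value B = 1000 permutations can
  produce); the planted mechanism concentrates affected nodes' degree in
  theta at the expense of alpha2, lowering their layer balance.
- The **gamma-band PC** shows no group difference — the generator plants a
  layer-imbalance effect, not a modular-structure effect, so the
  single-layer screen stays null and the joint threshold rule ("smallest k
  significant for both analyses") finds no qualifying k and falls back to
  the configured default k = 12 with a warning.
- The within-AD **score correlation is null here**: with the default score
  noise, between-subject MPC variation inside one group is too small to
  dominate, a useful reminder that a strong group difference does not by
  itself imply a within-group correlation.
- Classification from the top-3 ranked MPC features separates the groups
  completely (Acc = 100% with k_pc = 0), as expected for an effect this
  large; at smaller `delta` the accuracy degrades gracefully.

## Command line

An `mfnet` script (in `inst/cli/`) exposes the stages as subcommands:

```sh
mfnet simulate --spec spec.json --out cohort/ --seed 1
mfnet connectivity --manifest signals.json --measure coherence --out conn/
mfnet build --in cohort/HC001 --k 12 --out mx/
mfnet metrics --in mx/ --out metrics/
mfnet pipeline --manifest cohort/manifest.json --out results/ --seed 1
```

All on-disk formats are plain text: header-less CSV for matrices (6
decimals), TSV for metrics and edge lists (0-based node indices), JSON for
manifests, configs and results. Every pipeline run stamps its outputs with
a config hash and seed for exact re-runs.
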