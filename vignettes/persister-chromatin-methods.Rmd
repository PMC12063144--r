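---
title: "Methods: chromatin accessibility analysis of drug-tolerant persister subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin accessibility analysis of drug-tolerant persister subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persistATAC)
```

# Scientific setting

Targeted-therapy persistence in oncogene-driven cancers is increasingly
understood as a chromatin phenomenon: under drug, a minority of cells
survives not through new mutations but by shifting to alternative
transcriptional states. Single-cell ATAC-seq resolves these drug-tolerant
persister (DTP) subpopulations directly — one subpopulation may adopt an
alternative lineage program marked by its own transcription-factor motifs,
while another globally loses accessibility over broad repressive chromatin
domains.

`persistATAC` implements the full analysis path for such an experiment:
per-cell quality control, feature matrices from raw fragments, embedding and
clustering, marker statistics, projection of marker signatures onto a
directed regulatory network, a per-cell repressive-chromatin score with
graph-diffusion smoothing, cluster-path pseudotime, and
trajectory-differential motif statistics. Because real fragment files are
large and restricted, the package ships a synthetic fragment simulator with
planted ground truth; **the simulator's defaults are the study conditions**
under which every statistical claim in the test suite is evaluated.

# The generative model

`simulate_experiment(sim_config())` draws, per cell:

* a **population label** — by default `baseline`, `alveolar` (alternative
  lineage; its peaks carry `MOTIF_A` at 3x the background rate) and
  `repressed` (accessibility over broad domains multiplied by a depletion
  factor of 0.2), 300 cells each;
* a **sequencing depth** from a log-normal (default meanlog `log(3000)`,
  sdlog 0.5) — depth varies per cell, which is exactly the nuisance the
  TF-IDF/LSI depth-flagging must handle;
* **fragments** assigned to peaks, TSS-proximal windows, repressive domains
  and uniform background in configured proportions; population identity
  enters through a `marker_fold` multiplier (default 4) on the
  population's 60 marker-gene peaks and through the domain depletion
  factor;
* **doublets** (default 30) as pooled fragment sets from two cells of
  *distinct* populations at half depth each.

Output is a 10x-style `fragments.tsv.gz` (0-based half-open intervals; each
fragment contributes two Tn5 insertions, at `start` and `end - 1`), plus
gene/peak/domain/motif annotations and a ground-truth JSON.

What the generator deliberately does **not** emulate: sequence content, GC
bias, chromosome structure beyond two uniform chromosomes, fragment-length
periodicity, or copy-number variation. Those are irrelevant to the
arithmetic being tested and would only slow the suite down.

**Problem sizes are this package's own choice.** Defaults (900 cells, 2 x
5 Mb genome, 2,000 peaks, 8 domains of 100 kb) were sized so that a full
pipeline run takes under a minute on one CPU while every planted effect is
recoverable at the published thresholds; they are not taken from any
specific dataset.

# Per-cell quality control

Three filters, applied conjunctively by `apply_qc_filters` with the
defaults `min_fragments = 100`, `min_tss = 4`, `doublet_threshold = 1`
(kept: `n_fragments >= 100`, `tss_enrichment >= 4`,
`doublet_enrichment < 1`).

**TSS enrichment** is the per-cell insertion density within ±50 bp of a TSS
divided by the density in background bands 1,901–2,000 bp away on both
sides, with a +1 pseudocount in the background numerator.

**Synthetic-doublet kNN enrichment** is a reconstruction of the common
simulated-doublet strategy, reduced to its minimal form: average the
binarized tile profiles of random cell pairs (default `n_synthetic = 400`),
co-embed observed and synthetic cells, and score each observed cell by the
fraction of synthetic cells among its `k = 30` nearest neighbours relative
to the expected fraction, so 1 means "no more synthetic neighbours than
chance". Two numerical choices matter:

* the co-embedding runs TF-IDF/LSI **without re-binarization** — a synthetic
  doublet's averaged profile would otherwise collapse to the *union* of two
  cells' tiles and sit far from everything at twice the breadth;
* the co-embedding is deliberately compact (rank 8, top 2,000 tiles, a
  single LSI iteration): doublet geometry is a coarse property, and extra
  components only add noise to neighbour counts.

The score is calibrated (mean ≈ 1) only under an exchangeable null — a
single homogeneous population. With several distinct populations,
synthetic pairs are mostly cross-population hybrids that land *between*
clusters, so doublet-free cells inside clusters score below 1. That
structural depression is the detection signal, not a bias.

# Features

* **Tile matrix**: 500 bp genome tiles x cells, counting Tn5 insertions
  (two per fragment), so the grand total is exactly twice the fragment
  count — an invariant the tests exploit.
* **Gene scores**: insertions weighted 1 inside the gene body and
  `exp(-d/5000)` beyond it, up to 100 kb; per-cell totals are normalized to
  10,000. The distance tail means a fragment-level fold change is
  attenuated at the gene-score level (neighbouring genes leak into each
  other's scores).
* **Repression score**: for a set of broad repressive domains, the
  pseudocounted insertion density inside the pooled domains divided by the
  density in pooled ±2 kb flanks:
  `((n_dom + 1)/L_dom) / ((n_fl + 1)/L_fl)`. Flanks are clipped at
  chromosome ends and pooling is across all domains — a per-domain flank
  normalization would be an alternative reconstruction; pooling was chosen
  because single cells have too few insertions per individual domain for a
  stable per-domain ratio.
* **Motif deviations**: chromVAR-style — observed motif-peak insertion
  fraction versus the expectation from per-cell totals, z-scored against
  permuted peak sets matched on accessibility deciles. A motif whose
  permutation null is degenerate (all peaks, or a constant profile) is
  reported as 0 rather than an artifact of a ~1e-16 standard deviation.

# Embedding, clustering, trajectory

**Iterative LSI** (`tfidf_lsi`): binarize, TF-IDF with
`IDF = ln(1 + N/(1 + df))`, truncated SVD (`irlba`, default rank 30, signs
fixed for determinism). Iteration 2 re-selects the tiles most variable
across coarse-cluster pseudobulk log-CPM. Components with |Pearson r| >
0.75 against per-cell depth are flagged and excluded from all downstream
geometry.

**Clustering** (`snn_cluster`): shared-nearest-neighbour graph (k = 15)
with Jaccard edge weights, Leiden modularity at resolution 0.8.

**Smoothing** (`impute_smooth`): a MAGIC-style diffusion restricted to a
kNN graph (k = 15): Gaussian kernel with an adaptive bandwidth set to the
distance of the `ceiling(k/3)`-th neighbour, symmetrized, row-normalized,
applied `t = 3` times. The kNN truncation is load-bearing: a dense kernel
in a ~20-dimensional LSI space places substantial mass on other
populations and blurs the repression signal across cluster boundaries.
Constant vectors are preserved exactly (row-stochasticity), which the
acceptance tests check to machine precision.

**Pseudotime** (`pseudotime`): given an ordered cluster path of length
`L`, each cell is projected onto the segment between consecutive cluster
centroids (scalar projection clamped to [0, 1]) and mapped to
`100 * (i - 1 + proj) / L`. By default the pipeline orders clusters from
open to repressed chromatin, so the smoothed repression score *decreases*
along pseudotime.

# Statistics

**Markers** (`marker_features`): vectorized two-sided Wilcoxon rank-sum per
feature. The exact distribution (`pwilcox`) is used when the feature is
tie-free and both groups have n < 50 — matching `stats::wilcox.test`
defaults — otherwise the normal approximation with tie and continuity
corrections. Effect size is `log2((mean1 + 1)/(mean2 + 1))`; signatures are
selected at BH FDR ≤ 0.1 and |log2FC| ≥ 0.5.

**Signature overlap** (`hypergeom_overlap`): upper-tail hypergeometric
probability of observing at least the seen overlap between two gene sets in
a fixed universe; validated against exhaustive enumeration for all
universes N ≤ 12.

**Network projection and key drivers**: marker signatures are projected
onto a directed regulatory network (`project_signature`, undirected
expansion, 2 layers); `key_drivers` tests, for each node, the
hypergeometric enrichment of the signature within its directed ego
(downstream, h = 2), calling drivers at BH FDR ≤ 0.05 with at least 5
downstream nodes. Two layers (rather than one) is the reconstruction
chosen so that a driver whose children are themselves regulators is still
reachable from its signature. `simulate_network` plants drivers whose
children are signature genes, then adds ambient preferential-attachment
edges that never target the planted drivers; ambient in-degree is *not*
seeded from the planted edges, so driver recovery measures the statistic
rather than the generator's leakage.

**Trajectory-differential motifs**: motif deviations are binned along
pseudotime (50 bins, window 7), scored by the range of the smoothed bin
means, and tested against permutations of the pseudotime assignment
(default 200), so the minimum attainable p is `1/(n_perm + 1)`.

# Determinism

Every stochastic step takes an explicit seed; `run_pipeline` writes
per-stage provenance JSON (parameters + input checksums) and skips stages
whose provenance matches, and two runs with the same configuration are
byte-identical — enforced by an acceptance test that hashes every artifact
of two independent runs.

```{r example, eval = FALSE}
cfg <- pipeline_config(out_dir = "run")
run_pipeline(cfg)
```

See `analysis/` in the source repository for the numbered driver scripts
that reproduce the full evaluation, and `scripts/acceptance.R` for the
headline quantities.
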