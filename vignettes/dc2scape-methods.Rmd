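---
title: "Methods and design of dc2scape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of dc2scape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dc2scape` implements the statistical core of a dendritic-cell (DC)
heterogeneity analysis: distribution-based marker discovery on
diffusion-imputed single-cell expression, multi-scale diffusion geometry
with a sampled shortest-path robustness procedure, clustering-stability
quantification, cross-species cluster correspondence, and a lasso model
linking transcription-factor (TF) motif scores to differential chromatin
accessibility. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic generators do and do
not emulate.

## Preprocessing

Cell filtering applies three rules in a fixed order — mitochondrial
molecule fraction (strictly above the threshold removes the cell; default
0.20), unique genes detected (strictly fewer than `min_genes` removes;
mouse-spleen preset 1000), and total molecules (strictly more than
`min_molecules` required; human-spleen preset 6000, melanoma preset 1000;
a threshold of 0 disables the filter) — and the QC report itemizes the
removal count of each stage so reports are reproducible and auditable.
Gene filtering keeps genes detected in strictly more than `min_cells`
cells (default 10). Normalization divides each cell by its total, rescales
by the median total across cells, and takes log2 with a pseudocount of
0.1; the median factor is stored so the transform round-trips back to
counts exactly.

PCA operates on gene-centered, unscaled values (unit-variance scaling is
deliberately not applied: the downstream statistics depend on magnitude
structure) with a deterministic sign convention — the largest-magnitude
loading of each component is made positive. Signature scoring z-scores
each gene across cells before averaging, making genes of different
magnitudes commensurable; zero-variance genes contribute 0 rather than
NaN, and a raw-mean mode is available. Factor removal (`regress_out_factors`)
fits per-gene ordinary least squares on the factor scores with an
intercept and returns residual + gene mean, so genes orthogonal to all
factors pass through unchanged; zero-variance factors are dropped (they
are collinear with the intercept), and collinearity among the remaining
factors is a hard error naming the culprits.

## Diffusion geometry

The affinity kernel is adaptive Gaussian: cell *i* spreads
`exp(-(d_ij/σ_i)^α)` over its k nearest neighbors, with `σ_i` the distance
to its ka-th neighbor (defaults k = 30, ka = 10, α = 2; larger α gives the
heavier-tailed decay variant). The matrix is symmetrized by averaging and
self-affinities are set to 1 before Markov normalization — self-loops are
standard in diffusion constructions and keeping them explicit lets dense
oracles match the implementation bit for bit. Imputation powers the
operator against the data (`M^t X`, default t = 4) by repeated sparse
multiplication; a row-stochastic operator fixes constants, so imputation
commutes with gene-wise affine maps — a property the tests assert.

Diffusion components are computed from the symmetric conjugate
`D^{-1/2} A D^{-1/2}` (numerically stable, orthogonal eigenbasis) and
mapped back to right eigenvectors of the Markov operator; either route
gives the same components up to scaling, and the package fixes unit norm
and a positive largest-magnitude entry. The trivial stationary component
is dropped; eigenvalue 1 with multiplicity above one means a disconnected
graph and is an error rather than a silent wrong answer. The number of
informative components is chosen at the largest relative eigen gap
`(λ_i − λ_{i+1})/λ_i`, always overridable — any fixed choice made by
inspection can be reproduced by passing `n_selected`. Multi-scale
coordinates scale component i by `λ_i/(1−λ_i)` so Euclidean distance
approximates diffusion distance aggregated over all scales.

The stability sweep re-imputes over a (k, t) grid and reports the median
across genes of the squared Pearson correlation with a reference
imputation, excluding zero-variance genes. On the branching generator the
median R² between (k = 20, t = 3) and (k = 30, t = 4) exceeds 0.99 — the
package's structural mirror of the robustness claim this procedure is
designed to check on real data.

## Marker statistics

The signed earth mover's distance between within-cluster and
out-of-cluster expression is computed as the interval-width-weighted
integral of the absolute empirical-CDF difference — the true Wasserstein-1
distance, not an unweighted sum over grid points. This choice is testable:
the magnitude matches a greedy north-west-corner solution of the 1-D
transport linear program to 1e-9 in the suite. The sign follows the median
difference; exact median ties fall back to the mean difference, then to 0.
AUC is computed by rank statistics with tie correction in O(n log n) and
validated against all-pairs counting. Because ~50% molecule dropout caps a
raw count's discriminative AUC well below 1 even for a 4-fold marker,
marker statistics are intended for imputed values; a warning (not an
error) flags non-imputed input.

Selection is a conjunction: AUC beyond `auc_min` (0.99 default; negative
discriminators admitted when two-sided) and signed EMD outside
`μ ± k·σ`, with μ and σ the mean and SD of signed EMD across all genes of
the contrast, on the signed scale. Both the 3-SD and 4-SD conventions
ship as presets, since both appear in practice; a median/MAD robust
variant is a flag. A degenerate spread (σ = 0) is an error rather than a
vacuous threshold. The cell-number rescaling diagnostic recomputes EMD
with balanced subsampling to the smaller group (25 seeded repetitions
averaged) and reports the rank correlation with the unbalanced values.

## Clustering robustness

The adjusted Rand index uses the Hubert–Arabie contingency-table form.
Consolidation relabels each cluster to the reference group holding a
plurality of its cells; plurality ties are left unconsolidated with a
warning (the tie case is undefined in the source procedure, and not
consolidating is the conservative choice). The sweep clusters along two
axes (number of PCs at fixed k, and k at fixed PCs), consolidates every
solution, and summarizes all unordered pairwise ARIs per axis as
mean ± SD, retaining the full pairwise matrix so alternative summaries
(e.g. consecutive pairs) can be recomputed. The clusterer is a pure
function `(embedding, k, seed) → labels`, so graph-community tools can be
slotted in; the built-in convenience is a k-NN graph with greedy
modularity optimization — explicitly a stand-in, not a Phenograph
reimplementation.

## Trajectory path robustness

Shortest paths use an in-package Dijkstra with deterministic
tie-breaking (equal-cost alternatives resolve toward the smaller
predecessor index) rather than a library call, because reproducible paths
— not just reproducible lengths — are part of the contract. Edges are
treated as undirected with symmetric distances by default; the k-NN
relation itself is asymmetric and a directed mode is a flag. The k-l-NN
ensemble retains l of each cell's k edges uniformly per sample (fresh per
sample, one seeded RNG stream), recomputes the path, and reports the
failure rate of samples in which the target became unreachable; removing
edges can only lengthen paths, which the tests assert as a monotonicity
property.

"Within n neighbors of a path" is interpreted as membership in the union
over path nodes of each node's n-nearest-cell neighborhood (n = 20
default), with the dual reading (path node among the cell's n nearest)
available as an option. Membership proportions are compositions over the
proximal set, and step profiles flag steps above median + 5×MAD of the
path as discontinuity candidates. The ensemble default of 100 samples is
a package choice (the source procedure does not state its count); the
failure rate is always reported alongside.

## Correspondence analyses

Centroid correlation z-scores each gene across cluster centroids before
Pearson correlation over the shared (or ortholog-mapped) gene universe;
the z-score uses the sample SD (n−1). Many-to-many ortholog maps are
reduced to one-to-one by keeping uniquely mapping pairs and otherwise the
highest-total-expression partner (lexicographic when no totals are
given); the applied rule is logged.

Cluster signatures use one-vs-rest penalized binomial regression
(`cv.glmnet`, α = 0.99, 10 stratified folds, held-out AUC as the CV
measure) on genes with total count strictly above 300, after this
procedure's own normalization (median-total scaling, log2(x+1)).
Coefficients are reported at the AUC-maximizing penalty, with the one-SE
alternative always attached. Two behaviors of this estimator are worth
knowing and are documented in the tests: on cleanly separable clusters
the held-out AUC saturates and the L1 path keeps a *minimal* separating
subset of the true markers (the recovered support is pure but not
exhaustive), and on label-permuted data the CV-AUC curve drifts within
fold noise so the selected penalty does not reliably give an empty
support even though the held-out AUC stays at chance.

Variable-TF selection runs a classical one-way ANOVA F-test per TF across
clusters on per-cell values (clusters with fewer than 2 cells are
excluded with a warning), adjusts with Benjamini–Hochberg, and selects at
FDR < 1e-5 in each species, intersecting through the ortholog map. The
expression pre-filter default (mean normalized count > 10) is borrowed
from the TF-expression threshold used in the chromatin arm, as no
separate value is defined for this step. TF programs are clustered per
species on z-scored profiles under the cosine metric — implemented as
Euclidean k-NN on unit-normalized profiles, which is monotone-equivalent
to cosine distance — and the overlap matrix counts orthologous TFs shared
by each cluster pair; entries sum to the number of shared TFs by
construction. Because per-TF z-scoring removes offsets, programs must
differ in profile *shape* to be distinguishable; a block differing only
in mean level is invisible by design.

The signature shift test is a two-sided two-sample Kolmogorov–Smirnov
test of the signature genes' log2 fold changes against the full
background (signature included, matching the plotted-CDF convention),
with step curves exported for plotting.

## The chromatin arm

The summit atlas removes peaks of width ≤ 76 bp and off-list chromosomes,
rejects records whose summit falls outside the peak, and centers one
window per summit: `[summit − w/2, summit + w/2)` for even widths (the
150 bp default), 0-based half-open throughout. Peak–gene annotation
follows a strict precedence — promoter (summit within 2 kb of any TSS),
exonic (window overlaps an exon), intronic (window overlaps a gene body),
intergenic (within 50 kb of a gene), unclassified — so every peak gets
exactly one class; gene distance is measured window-edge to gene-span
edge (0 when overlapping) while TSS distance is summit to TSS, and both
anchors are documented because the source rules do not fix them.

The differential-accessibility stand-in is deliberately lightweight and
labeled as such at run time: median-of-ratios size factors, group-mean
log2 fold change with a 0.5 pseudocount, Welch t on log2-normalized
counts, BH adjustment. It is not a negative-binomial model; externally
computed tables are the recommended input and preserve the exact
published thresholds (FDR < 0.01, |log2FC| > 0.5). The significance call
additionally requires the peak to be reproducible in the condition where
it is more accessible; reproducibility flags are upstream inputs, never
computed here.

Motif scanning scores both strands at every window offset with
discretized log-odds weights (1e-3 bins); per-position p-values come from
the exact null distribution of the discretized score under the background,
computed by dynamic programming over the score lattice — the same
discretization is used for scanning and for the null, so exact-p oracle
tests hold to enumeration over all 4^L sequences. The reverse strand uses
the reversed, base-complemented integer weight matrix, keeping the two
strands exactly symmetric. A window position containing an ambiguous base
contributes −∞ and the offset is skipped. Backgrounds are uniform by
default with a 0-order from-sequence option. The inner scan loop is
compiled (Rcpp) with a plain-R reference implementation retained as a
cross-check in the tests. Feature values are best-significant-hit scores
(hit-count and sum modes were considered and rejected as defaults because
the best hit is the least sensitive to window length).

The association model ranks peaks by normalized mean count, keeps the top
20,000 (all, when fewer), standardizes features, and fits a lasso over a
100-point penalty path with 5-fold cross-validation minimizing held-out
squared error; reported performance is the mean across folds of the
Spearman ρ between held-out predictions and observed fold changes —
selection and evaluation metrics are deliberately separated. Folds with a
constant response are excluded from ρ with a warning; constant held-out
predictions (an empty model) score ρ = 0. Coefficients are reported on
the standardized scale with de-standardized values alongside. Per-gene
peak sets are compared against all peaks (the gene's own peaks included,
matching the "all peaks" background convention) with a two-sided
Mann–Whitney U test and BH adjustment across tested genes.

## Synthetic generators

`make_sc_counts` emulates discrete subsets with planted markers, a shared
cell-cycle program, lognormal library sizes and molecule dropout:
per-cell expected profiles are normalized and realized as Poisson counts,
then *binomially thinned* at the dropout rate — the standard model of
capture inefficiency, in which each molecule is lost independently.
Defaults: 2,000 cells × 2,000 genes, 3 subsets, 10 markers per subset at
2 log2-units (4-fold; subset-defining DC markers are typically ≥ 4-fold),
50% dropout, median library 2,000 molecules (sdlog 0.35), lognormal gene
baselines (sdlog 1), 15% cycling cells. Marker and cycle genes sit at the
90th percentile of the baseline distribution: planted markers emulate
robustly detected subset-defining genes, not median-expression genes —
at the median baseline the planted truth is statistically unidentifiable
by any method, which would make the generator useless as ground truth.

`make_branching_traj` draws pseudotime uniformly, assigns cells past the
branch point to two branches, and gives each gene a smooth logistic trend
that freezes at its branch-point value on the off branch, plus Gaussian
noise (defaults 1,000 cells × 100 genes, branch point 0.4, noise SD 0.2).
`make_atac_toy` builds a random genome with evenly spaced summit windows,
random PWMs with controllable information content, consensus instances of
the causal motifs implanted into 25% of windows, fold changes
`y = Xw* + ε` with noise scaled to a signal-to-noise ratio of
sd(signal)/sd(noise) = 2 (R² = 0.8), negative-binomial counts in two
conditions, and gene models placed so annotation exercises every class
(which requires ≥ 100 peaks). `make_bulk_profiles` adds log-scale noise to
centroids and exponentiates.

What the generators do *not* emulate: ambient RNA, doublets, batch
effects, overdispersion beyond Poisson (negative-binomial counts are an
option, not the default), UMI saturation, sequence composition bias, or
correlated motif co-occurrence. Passing tests on this ground truth
demonstrates that the statistics and their selection rules behave as
specified — recovery on real data additionally depends on those
unmodeled effects.

## Problem sizes and determinism

The shipped validation runs at the generators' default sizes (2,000 ×
2,000 expression matrices; 1,000-cell trajectories; 2,000-peak, 120-motif
chromatin toys), chosen so a complete run of the suite and the acceptance
script stays comfortable on a single CPU. Every stochastic step takes an
explicit seed and every generator is a pure function of (configuration,
seed); `run_recipe` refuses configs with unknown keys and writes a
manifest (package version, recipe, seed, resolved parameters) next to its
outputs, so identical configs reproduce identical results modulo
timestamps.

## Known limitations

- The differential-accessibility stand-in is a Welch-t approximation, not
  a count model; use external tables for publication-grade calls.
- The per-TF best-motif reduction expects an externally supplied
  enrichment ranking; the built-in prevalence-against-shuffled fallback is
  a rough screen, not an enrichment statistic.
- Elastic-net cluster signatures on separable data recover a minimal
  marker subset (see above); interpret supports as sufficient, not
  exhaustive, marker sets.
- Dense distance matrices bound the practical scale to a few thousand
  cells; that is the regime the procedures were designed for.
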