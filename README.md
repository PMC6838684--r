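# dc2scape

Statistical machinery for dissecting dendritic-cell (DC) heterogeneity from
single-cell RNA-seq and ATAC-seq data. Classical DCs split into cDC1 and
cDC2 compartments, and cDC2s further into T-bet⁺ (cDC2A) and T-bet⁻ (cDC2B)
lineages; resolving such closely related subsets needs statistics that work
on whole expression distributions rather than means, geometry that respects
a differentiation continuum, and a way to tie transcription-factor (TF)
motifs to chromatin changes. `dc2scape` implements that toolkit as an R
package, together with synthetic-data generators that plant known ground
truth so every stage can be validated end to end without any external
download.

## What the package computes

**Distribution-based marker discovery.** For a gene *g* and a cell cluster
versus the rest, the signed earth mover's distance on (diffusion-imputed)
expression is the Wasserstein-1 distance

EMD(g) = ± ∫ |F_in(x) − F_out(x)| dx,

signed by the direction of the median shift, paired with the area under the
ROC curve (AUC = Mann–Whitney U / n₁n₂) of the gene as a one-gene
classifier. Markers are selected jointly: AUC ≥ 0.99 (or ≤ 0.01) and signed
EMD outside μ_EMD ± kσ_EMD computed across all genes of the contrast
(k = 3 by default, 4 as the stricter preset).

**Diffusion geometry.** An adaptive Gaussian kernel
exp(−(d_ij/σ_i)²) with σ_i the distance to the ka-th neighbor (k = 30,
ka = 10) is symmetrized and row-normalized into a Markov operator M;
imputation is Mᵗ·X (t = 4), and diffusion maps are the eigenvectors of the
symmetric conjugate of M with coordinates scaled by λ/(1−λ) to approximate
multi-scale diffusion distances.

**Trajectory robustness.** On k-NN graphs of diffusion distances (k = 15),
exact Dijkstra shortest paths from a progenitor cell to terminal states are
re-sampled on k-l-NN subgraphs (l = 5 of each cell's edges retained per
sample); per-cell path-proximity probabilities, cluster composition of the
path neighborhood, and step-size outlier profiles quantify whether a
differentiation route is continuous and stays on its own branch.

**Clustering stability.** Solutions across a grid of input PCs and
neighborhood sizes are consolidated into reference groups by plurality
membership and compared with the adjusted Rand index, reported as
mean ± SD per sweep axis.

**Cross-species correspondence.** Z-scored cluster-centroid Pearson
correlation through an ortholog map, one-vs-rest elastic-net cluster
signatures (binomial `cv.glmnet`, α = 0.99, held-out AUC), ANOVA-selected
variable TFs (BH FDR < 1e-5 in both species), cosine-metric TF program
clustering with overlap counts, core-signature derivation from bulk
differential tables (|log2FC| > 1.5, mean count ≥ 50, FDR < 0.01), and a
two-sided Kolmogorov–Smirnov test for signature shifts in fold-change
distributions.

**Motif → accessibility lasso.** ATAC summit windows (150 bp) are scanned
with position weight matrices using log-odds scores and *exact* per-position
p-values from a dynamic program over the discretized score lattice
(hits at p < 5e-4); after prevalence filtering (1–40 % of windows), a lasso
y ~ Xw links per-peak accessibility log2 fold changes to motif scores, with
5-fold cross-validation and held-out Spearman ρ as the performance metric.
Per-gene peak sets are tested against all peaks with a Mann–Whitney U test
("diamond plot" data).

## Worked example

```r
library(dc2scape)

# simulate 2,000 cells x 2,000 genes: 3 subsets, 10 planted markers each
# (4-fold), shared cell-cycle program, 50% dropout
sim <- make_sc_counts(seed = 1)

filtered <- filter_genes(filter_cells(sim$counts, min_genes = 0)$counts,
                         min_cells = 10)$counts
expr   <- normalize_counts(filtered)
pca    <- compute_pca(expr, n_components = 20)
op     <- markov_normalize(adaptive_affinity(pca$scores, k = 30, ka = 10))
imp    <- impute_expression(expr, op, t = 4)
tab    <- marker_table(imp, sim$truth$labels[filtered$cell_ids])
sel    <- select_markers(tab, auc_min = 0.99, emd_sd_multiplier = 3)

length(unique(sel$gene))                                  # 30
mean(sim$truth$markers$gene %in% sel$gene)                # 1  (sensitivity)
mean(!(unique(sel$gene) %in% sim$truth$markers$gene))     # 0  (false rate)
```

All 30 planted markers are recovered with no false selections: imputation
restores the discriminative power that dropout removes (a planted marker's
raw-count AUC is ~0.89; after diffusion imputation it reaches 1.0, crossing
the 0.99 selection threshold).

The same one-call pipelines are available as recipes:

```r
out <- run_recipe(list(seed = 1), "sc_markers")   # identical result + manifest
atac <- run_recipe(list(seed = 1), "atac")        # motif-lasso arm
```

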