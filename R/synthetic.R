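#' Simulate a single-cell count matrix with planted subset markers
#'
#' Cells belong to discrete subsets; each subset has planted marker genes
#' whose expression rate is multiplied by `2^marker_effect` in that subset.
#' A shared cell-cycle program scales a set of cycle genes by per-cell cycle
#' intensity. Per-cell expected profiles are normalized and realized as
#' Poisson counts at lognormal library sizes, then binomially thinned by the
#' dropout rate (each molecule independently lost with probability
#' `dropout`, the standard thinning model of capture inefficiency). The
#' generator is a pure function of its configuration and seed.
#'
#' Defaults emulate a modest droplet experiment: 2,000 cells by 2,000 genes,
#' 3 subsets with 10 markers each at a 2 log2-unit (4-fold) effect, 50%
#' dropout, lognormal gene baselines, median library 2,000 molecules, and a
#' cycling subpopulation of 15% of cells.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_subsets number of discrete subsets (equal proportions).
#' @param n_markers planted markers per subset.
#' @param marker_effect subset log2 fold effect of each marker (default 2).
#' @param n_cycle_genes genes in the shared cell-cycle program (default 50).
#' @param cycle_effect log2 effect of the program in cycling cells
#'   (default 1).
#' @param cycle_frac fraction of cycling cells (default 0.15).
#' @param lib_median median library size in molecules (default 2000).
#' @param lib_sdlog lognormal sdlog of library sizes (default 0.35).
#' @param baseline_sdlog lognormal sdlog of gene baseline rates (default 1).
#' @param marker_baseline_quantile quantile of the baseline-rate
#'   distribution assigned to marker and cycle genes (default 0.9): planted
#'   markers emulate subset-defining genes, which are robustly detected
#'   rather than median-expression genes.
#' @param dropout per-molecule loss probability for binomial thinning
#'   (default 0.5); 1 gives an all-zero matrix.
#' @param seed RNG seed.
#' @return list with `counts` (a [dc_counts()]) and `truth` (class
#'   `dc_sctruth`): `labels`, `markers` (data.frame gene/subset/effect),
#'   `cycle_genes`, `cycle_intensity`, `library_size`, `dropout`.
#' @export
make_sc_counts <- function(n_cells = 2000, n_genes = 2000, n_subsets = 3,
                           n_markers = 10, marker_effect = 2,
                           n_cycle_genes = 50, cycle_effect = 1,
                           cycle_frac = 0.15, lib_median = 2000,
                           lib_sdlog = 0.35, baseline_sdlog = 1,
                           marker_baseline_quantile = 0.9,
                           dropout = 0.5, seed = 1) {
  stopifnot(dropout >= 0, dropout <= 1, n_subsets >= 1,
            n_markers * n_subsets + n_cycle_genes <= n_genes)
  with_seed(seed, {
    labels <- paste0("subset_", rep_len(seq_len(n_subsets), n_cells))
    labels <- sample(labels)
    baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = baseline_sdlog)
    special <- sample.int(n_genes, n_subsets * n_markers + n_cycle_genes)
    marker_idx <- matrix(special[seq_len(n_subsets * n_markers)],
                         nrow = n_subsets)
    cycle_idx <- special[-seq_len(n_subsets * n_markers)]
    # markers and cycle genes emulate robustly detected genes: fixed at a
    # high quantile of the baseline distribution so planted structure is
    # identifiable, as subset-defining genes are in real data
    baseline[special] <- stats::quantile(baseline, marker_baseline_quantile)
    log2_rate <- matrix(rep(log2(baseline), each = n_cells), n_cells, n_genes)
    for (s in seq_len(n_subsets)) {
      i <- labels == paste0("subset_", s)
      log2_rate[i, marker_idx[s, ]] <- log2_rate[i, marker_idx[s, ]] +
        marker_effect
    }
    cycling <- stats::runif(n_cells) < cycle_frac
    intensity <- ifelse(cycling, abs(stats::rnorm(n_cells)), 0)
    log2_rate[, cycle_idx] <- log2_rate[, cycle_idx] +
      intensity * cycle_effect
    rate <- 2^log2_rate
    if (any(!is.finite(rate))) stop("infeasible config: rates overflow")
    rate <- rate / rowSums(rate)
    libs <- stats::rlnorm(n_cells, meanlog = log(lib_median), sdlog = lib_sdlog)
    mu <- rate * libs
    counts <- matrix(stats::rpois(length(mu), mu), n_cells, n_genes)
    if (dropout > 0)
      counts <- matrix(stats::rbinom(length(mu), size = counts,
                                     prob = 1 - dropout),
                       n_cells, n_genes)
    rownames(counts) <- sprintf("cell_%04d", seq_len(n_cells))
    colnames(counts) <- sprintf("gene_%04d", seq_len(n_genes))
    markers <- data.frame(
      gene = colnames(counts)[as.vector(t(marker_idx))],
      subset = paste0("subset_", rep(seq_len(n_subsets), each = n_markers)),
      effect = marker_effect, stringsAsFactors = FALSE)
    truth <- structure(list(labels = stats::setNames(labels, rownames(counts)),
                            markers = markers,
                            cycle_genes = colnames(counts)[cycle_idx],
                            cycle_intensity = intensity,
                            library_size = libs, dropout = dropout),
                       class = "dc_sctruth")
    list(counts = dc_counts(counts), truth = truth)
  })
}

# Smooth increasing/decreasing logistic trend on [0, 1].
logistic_trend <- function(pt, center, steepness, sign) {
  sign / (1 + exp(-steepness * (pt - center)))
}

#' Simulate a branching low-dimensional expression trajectory
#'
#' Cells carry a latent pseudotime in \[0, 1\] and a branch label: `root`
#' before the branch point, `A` or `B` after. Genes follow smooth logistic
#' trends over pseudotime; branch-specific genes diverge after the branch
#' point (the off-branch trend is frozen at its branch-point value), shared
#' genes follow one trend throughout. Gaussian noise is added on top.
#'
#' @param n_cells,n_genes dimensions (defaults 1000 x 100).
#' @param branch_point pseudotime of the bifurcation, in (0, 1)
#'   (default 0.4).
#' @param noise_sd Gaussian noise SD (default 0.2).
#' @param frac_branch_genes fraction of genes specific to each branch
#'   (default 0.25 per branch).
#' @param seed RNG seed.
#' @return list with `expr` (a [dc_expr()], `state = "normalized"`) and
#'   `truth` (class `dc_trajtruth`): `pseudotime`, `branch`, `gene_class`.
#' @export
make_branching_traj <- function(n_cells = 1000, n_genes = 100,
                                branch_point = 0.4, noise_sd = 0.2,
                                frac_branch_genes = 0.25, seed = 1) {
  stopifnot(branch_point > 0, branch_point < 1)
  with_seed(seed, {
    pt <- sort(stats::runif(n_cells))
    branch <- ifelse(pt <= branch_point, "root",
                     ifelse(stats::runif(n_cells) < 0.5, "A", "B"))
    n_a <- round(frac_branch_genes * n_genes)
    gene_class <- c(rep("A", n_a), rep("B", n_a),
                    rep("shared", n_genes - 2 * n_a))
    center <- stats::runif(n_genes, 0.1, 0.9)
    steep <- stats::runif(n_genes, 4, 12)
    sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
    amp <- stats::runif(n_genes, 1, 3)
    expr <- matrix(0, n_cells, n_genes)
    for (g in seq_len(n_genes)) {
      tr <- amp[g] * logistic_trend(pt, center[g], steep[g], sgn[g])
      if (gene_class[g] %in% c("A", "B")) {
        off <- branch != gene_class[g] & branch != "root"
        frozen <- amp[g] * logistic_trend(branch_point, center[g], steep[g],
                                          sgn[g])
        tr[off] <- frozen
        # the on-branch trend keeps evolving only after the branch point
        pre <- pt <= branch_point
        tr[pre] <- amp[g] * logistic_trend(pt[pre], center[g], steep[g],
                                           sgn[g])
      }
      expr[, g] <- tr
    }
    expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                          n_cells, n_genes)
    rownames(expr) <- sprintf("cell_%04d", seq_len(n_cells))
    colnames(expr) <- sprintf("gene_%03d", seq_len(n_genes))
    truth <- structure(list(pseudotime = stats::setNames(pt, rownames(expr)),
                            branch = stats::setNames(branch, rownames(expr)),
                            gene_class = stats::setNames(gene_class,
                                                         colnames(expr))),
                       class = "dc_trajtruth")
    list(expr = dc_expr(expr, state = "normalized"), truth = truth)
  })
}

random_ppm <- function(length, dominant_prob = 0.85) {
  dom <- sample.int(4, length, replace = TRUE)
  ppm <- matrix((1 - dominant_prob) / 3, length, 4)
  ppm[cbind(seq_len(length), dom)] <- dominant_prob
  ppm
}

# Consensus instance: implanted sites are high-affinity (near-consensus)
# occurrences, guaranteeing they clear the scanner's significance threshold.
consensus_instance <- function(motif) {
  c("A", "C", "G", "T")[apply(motif$ppm, 1, which.max)]
}

#' Simulate a toy ATAC atlas with planted motif-accessibility effects
#'
#' Generates a random genome with evenly spaced peaks, a panel of random
#' position weight matrices, and motif instances implanted into a fraction
#' of the windows for the `n_active_motifs` causal motifs. The per-peak
#' accessibility log2 fold change is a sparse linear function of the
#' (standardized) scanned motif scores, `y = X w* + noise`, with the noise
#' SD set so that `sd(signal)/sd(noise) = snr`; fold changes are realized as
#' two-condition negative-binomial counts. Gene models are placed so that
#' peak annotation covers every class (promoter, exonic, intronic,
#' intergenic, unclassified).
#'
#' @param n_peaks,n_motifs panel dimensions (defaults 2000 x 120).
#' @param n_active_motifs causal motifs (default 5).
#' @param effect_size |w*| of each causal motif, alternating sign
#'   (default 1; must be >= 0.5 for the planted effects to dominate at the
#'   default SNR). 0 gives a null configuration.
#' @param snr signal-to-noise ratio sd(signal)/sd(noise) (default 2).
#' @param n_genes genes in the toy annotation (default 20).
#' @param n_reps replicates per condition (default 3).
#' @param motif_length PWM length (default 8).
#' @param implant_frac fraction of windows receiving an instance of each
#'   active motif (default 0.25).
#' @param window window width (default 150).
#' @param mean_count baseline mean accessibility count (default 100).
#' @param nb_dispersion negative-binomial dispersion (default 0.05).
#' @param seed RNG seed.
#' @return list with `genome` (`DNAStringSet`), `peaks` (data.frame for
#'   [build_atlas()]), `genes` (a [gene_model()]), `motifs` (list of
#'   [motif_model()]), `counts` (peaks x samples), `groups`, `reproducible`,
#'   and `truth` (class `dc_atactruth`): `w_star`, `active_motifs`,
#'   `log2fc`, `implanted` (list of window indices per active motif).
#' @export
make_atac_toy <- function(n_peaks = 2000, n_motifs = 120,
                          n_active_motifs = 5, effect_size = 1, snr = 2,
                          n_genes = 20, n_reps = 3, motif_length = 8,
                          implant_frac = 0.25, window = 150,
                          mean_count = 100, nb_dispersion = 0.05, seed = 1) {
  stopifnot(n_active_motifs <= n_motifs,
            n_peaks >= 100)   # full annotation-class coverage needs room
  with_seed(seed, {
    spacing <- 1000
    chrom_len <- (n_peaks + 2) * spacing
    bases <- c("A", "C", "G", "T")
    genome_chars <- sample(bases, chrom_len, replace = TRUE)
    summits <- spacing * seq_len(n_peaks) + sample(-100:100, n_peaks,
                                                   replace = TRUE)
    half_peak <- sample(60:200, n_peaks, replace = TRUE)
    peaks <- data.frame(chrom = "chr1",
                        start = summits - half_peak,
                        end = summits + half_peak,
                        summit = summits,
                        peak_id = sprintf("peak_%05d", seq_len(n_peaks)),
                        stringsAsFactors = FALSE)
    motifs <- lapply(seq_len(n_motifs), function(m)
      motif_model(sprintf("motif_%03d", m), random_ppm(motif_length)))
    active <- sort(sample.int(n_motifs, n_active_motifs))
    implanted <- list()
    half <- floor(window / 2)
    for (m in active) {
      wins <- sort(sample.int(n_peaks, round(implant_frac * n_peaks)))
      implanted[[motifs[[m]]$id]] <- wins
      inst <- consensus_instance(motifs[[m]])
      for (wdw in wins) {
        offset <- sample.int(window - motif_length + 1, 1) - 1
        pos <- summits[wdw] - half + offset
        genome_chars[(pos + 1):(pos + motif_length)] <- inst
      }
    }
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "chr1"
    atlas <- build_atlas(peaks, window = window, chromosomes = "chr1")
    hits <- scan_motifs(extract_windows(genome, atlas), motifs)
    w_star <- stats::setNames(numeric(n_motifs), colnames(hits$scores))
    w_star[active] <- effect_size * rep_len(c(1, -1), n_active_motifs)
    Xs <- zscore_cols(hits$scores)
    signal <- as.numeric(Xs %*% w_star)
    noise_sd <- if (stats::sd(signal) > 0) stats::sd(signal) / snr else 1
    y <- signal + stats::rnorm(n_peaks, sd = noise_sd)
    base_mu <- stats::rlnorm(n_peaks, meanlog = log(mean_count), sdlog = 0.5)
    mu_a <- base_mu * 2^(y / 2)
    mu_b <- base_mu * 2^(-y / 2)
    size <- 1 / nb_dispersion
    counts <- cbind(
      matrix(stats::rnbinom(n_peaks * n_reps, mu = mu_a, size = size),
             n_peaks, n_reps),
      matrix(stats::rnbinom(n_peaks * n_reps, mu = mu_b, size = size),
             n_peaks, n_reps))
    rownames(counts) <- atlas$peak_id
    colnames(counts) <- c(paste0("condA_rep", seq_len(n_reps)),
                          paste0("condB_rep", seq_len(n_reps)))
    groups <- factor(rep(c("condA", "condB"), each = n_reps),
                     levels = c("condA", "condB"))
    reproducible <- matrix(TRUE, n_peaks, 2,
                           dimnames = list(atlas$peak_id,
                                           c("condA", "condB")))
    genes <- toy_gene_model(summits, chrom_len, window)
    truth <- structure(list(w_star = w_star,
                            active_motifs = names(w_star)[active],
                            log2fc = stats::setNames(y, atlas$peak_id),
                            implanted = implanted, noise_sd = noise_sd),
                       class = "dc_atactruth")
    list(genome = genome, peaks = peaks, atlas = atlas, genes = genes,
         motifs = motifs, hits = hits, counts = counts, groups = groups,
         reproducible = reproducible, truth = truth)
  })
}

# Gene models anchored on well-separated summits so that annotation covers
# every class: promoter (TSS at an anchor summit), exonic (exon over a
# window far from any TSS), intronic (window inside a gene body, no exon),
# intergenic (gene 10 kb away) and unclassified (peaks beyond 50 kb of all
# genes). Anchors are >= 9 summit spacings apart so the 2 kb promoter
# radius of one gene cannot swallow another anchor's window.
toy_gene_model <- function(summits, chrom_len, window) {
  s <- summits
  stopifnot(length(s) >= 100)
  a1 <- s[1]; a2 <- s[10]; a3 <- s[20]; a4 <- s[30]
  genes <- data.frame(
    gene_id = c("geneP", "geneE", "geneI", "geneD"),
    chrom = "chr1",
    strand = c("+", "+", "-", "+"),
    start = c(a1 - 500, a2 - 5000, a3 - 5000, a4 + 10000),
    end = c(a1 + 300, a2 + 5000, a3 + 5000, a4 + 15000),
    stringsAsFactors = FALSE)
  tss <- data.frame(gene_id = c("geneP", "geneE", "geneI", "geneD"),
                    pos = c(a1, a2 - 5000, a3 + 5000, a4 + 10000))
  exons <- data.frame(
    gene_id = c("geneP", "geneE", "geneI", "geneD"),
    start = c(a1 - 500, a2 - window, a3 - 5000, a4 + 10000),
    end = c(a1 - 400, a2 + window, a3 - 4900, a4 + 10100))
  gene_model(genes, tss, exons)
}

#' Simulate bulk expression profiles from cluster centroids
#'
#' Each replicate is a centroid plus Gaussian noise on the log2 scale,
#' exponentiated back to normalized counts.
#'
#' @param centroids clusters x genes matrix (e.g. [centroid_profiles()]).
#' @param n_replicates replicates per centroid (default 3).
#' @param noise_sd log2-scale noise SD (default 0.2).
#' @param seed RNG seed.
#' @return samples x genes matrix with rownames `<cluster>_rep<i>`.
#' @export
make_bulk_profiles <- function(centroids, n_replicates = 3, noise_sd = 0.2,
                               seed = 1) {
  centroids <- as.matrix(centroids)
  with_seed(seed, {
    out <- do.call(rbind, lapply(rownames(centroids), function(cl) {
      reps <- vapply(seq_len(n_replicates), function(r)
        2^(centroids[cl, ] + stats::rnorm(ncol(centroids), sd = noise_sd)),
        numeric(ncol(centroids)))
      t(reps)
    }))
    rownames(out) <- as.vector(t(outer(rownames(centroids),
                                       seq_len(n_replicates),
                                       function(a, b) paste0(a, "_rep", b))))
    colnames(out) <- colnames(centroids)
    out
  })
}
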