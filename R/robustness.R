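#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement from the contingency table:
#' `(sum C(n_ij,2) - E) / (max - E)`. Invariant to label permutation;
#' identical partitions score 1, random partitions score about 0.
#'
#' @param p1,p2 label vectors over the same cells. Named vectors are aligned
#'   by name; unnamed vectors are compared positionally.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions are defined on different cell sets")
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions must cover the same cells")
  }
  tab <- table(as.character(p1), as.character(p2))
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Consolidate clusters into reference groups by plurality membership
#'
#' Each cluster of `labels` whose plurality of cells falls inside one
#' reference group (cells of the reference partition whose label belongs to
#' that group) is relabeled to the group's name; clusters whose plurality
#' lies outside all groups keep their label, and plurality ties between
#' groups are left unconsolidated with a warning. Idempotent.
#'
#' @param labels partition to consolidate (per-cell labels).
#' @param reference per-cell labels of the reference partition (same cells,
#'   same order or matching names).
#' @param reference_groups named list of reference-label sets.
#' @return relabeled per-cell character vector.
#' @export
consolidate <- function(labels, reference, reference_groups) {
  labels <- as.character(labels)
  reference <- as.character(reference)
  if (length(labels) != length(reference))
    stop("labels and reference must cover the same cells")
  if (any(lengths(reference_groups) == 0)) stop("empty reference group")
  if (is.null(names(reference_groups)))
    names(reference_groups) <- paste0("group_", seq_along(reference_groups))
  cell_group <- rep(NA_character_, length(reference))
  for (g in names(reference_groups))
    cell_group[reference %in% reference_groups[[g]]] <- g
  out <- labels
  for (cl in unique(labels)) {
    i <- labels == cl
    counts <- table(factor(cell_group[i], levels = names(reference_groups)))
    n_outside <- sum(i) - sum(counts)
    best <- max(counts)
    if (best > n_outside && best > 0) {
      winners <- names(counts)[counts == best]
      if (length(winners) > 1) {
        warning("cluster '", cl, "': plurality tie between reference groups; left unconsolidated")
      } else {
        out[i] <- winners
      }
    }
  }
  out
}

#' Convenience k-NN modularity clusterer
#'
#' Builds an unweighted undirected k-NN graph (Euclidean metric on the
#' embedding, union of directed neighbor relations) and partitions it with
#' greedy modularity optimization (igraph's fast-greedy community
#' detection), with seeded tie-breaking. A convenience stand-in for
#' community-detection clusterers such as Phenograph, not a reimplementation
#' of them; any labeling procedure with the same `(embedding, k, seed)`
#' signature can be used in its place.
#'
#' @param embedding cells x K numeric matrix.
#' @param k number of nearest neighbors (>= 2).
#' @param seed RNG seed (determinism contract: same seed, same labels).
#' @return character label per cell.
#' @export
default_clusterer <- function(embedding, k = 30, seed = 1) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k < 2) stop("k must be >= 2")
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- knn_query(multiscale_distances(embedding), k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_fast_greedy(g)))
  as.character(as.integer(memb))
}

#' Clustering robustness sweep over PCs and k
#'
#' Re-clusters the data along two parameter axes (number of input principal
#' components at fixed `fixed_k`, and neighborhood size k at fixed
#' `fixed_n_pcs`), consolidates every solution into the reference groups,
#' and summarizes all unordered pairwise adjusted Rand indices along each
#' axis as mean and SD. The full pairwise matrices are retained so
#' alternative summaries can be recomputed. Clusterer failures at a grid
#' point are recorded and the point excluded.
#'
#' @param expr expression ([dc_expr()] or matrix) from which PCs are taken.
#' @param clusterer function `(embedding, k, seed) -> labels`; default
#'   [default_clusterer()].
#' @param n_pcs_values,k_values grid axes.
#' @param reference per-cell reference labels.
#' @param reference_groups named list of reference-label sets (see
#'   [consolidate()]).
#' @param fixed_k k used while sweeping PCs.
#' @param fixed_n_pcs number of PCs used while sweeping k.
#' @param seed passed to the clusterer.
#' @return object of class `dc_robustness` with per-axis `values`,
#'   `ari_matrix`, `mean`, `sd`, plus `failures`.
#' @export
robustness_sweep <- function(expr, clusterer = default_clusterer,
                             n_pcs_values, k_values, reference,
                             reference_groups, fixed_k = 30,
                             fixed_n_pcs = 20, seed = 1) {
  v <- as_expr_values(expr)
  max_pcs <- max(c(n_pcs_values, fixed_n_pcs))
  pca <- compute_pca(v, n_components = min(max_pcs, min(dim(v))))
  failures <- list()
  run_point <- function(n_pcs, k, tag) {
    emb <- pca$scores[, seq_len(min(n_pcs, ncol(pca$scores))), drop = FALSE]
    tryCatch(consolidate(clusterer(emb, k, seed), reference, reference_groups),
             error = function(e) {
               failures[[tag]] <<- conditionMessage(e)
               NULL
             })
  }
  sweep_axis <- function(values, solutions) {
    ok <- !vapply(solutions, is.null, logical(1))
    sols <- solutions[ok]
    m <- length(sols)
    ari <- matrix(NA_real_, m, m, dimnames = list(values[ok], values[ok]))
    diag(ari) <- 1
    if (m >= 2) {
      for (i in seq_len(m - 1)) for (j in (i + 1):m)
        ari[i, j] <- ari[j, i] <- adjusted_rand_index(sols[[i]], sols[[j]])
    }
    pair_vals <- ari[upper.tri(ari)]
    list(values = values[ok], ari_matrix = ari, solutions = sols,
         mean = mean(pair_vals), sd = stats::sd(pair_vals))
  }
  pc_sols <- lapply(n_pcs_values, function(p)
    run_point(p, fixed_k, paste0("pcs=", p)))
  k_sols <- lapply(k_values, function(k)
    run_point(fixed_n_pcs, k, paste0("k=", k)))
  structure(list(pc_sweep = sweep_axis(n_pcs_values, pc_sols),
                 k_sweep = sweep_axis(k_values, k_sols),
                 failures = failures), class = "dc_robustness")
}

#' @export
print.dc_robustness <- function(x, ...) {
  cat(sprintf("Clustering robustness: RI_PC = %.3f +/- %.3f, RI_k = %.3f +/- %.3f\n",
              x$pc_sweep$mean, x$pc_sweep$sd, x$k_sweep$mean, x$k_sweep$sd))
  if (length(x$failures) > 0)
    cat("failed grid points:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
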