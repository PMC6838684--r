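#' Named quality-control presets
#'
#' Threshold bundles used for the splenic mouse, splenic human and melanoma
#' datasets respectively. All values can be overridden in [filter_cells()].
#' @export
qc_presets <- list(
  mouse_spleen = list(max_mito_frac = 0.20, min_genes = 1000, min_molecules = 0),
  human_spleen = list(max_mito_frac = 0.20, min_genes = 0, min_molecules = 6000),
  melanoma     = list(max_mito_frac = 0.20, min_genes = 0, min_molecules = 1000)
)

new_qc_report <- function(stage_names, removed, n_in, n_out, axis) {
  structure(list(axis = axis, n_in = n_in, n_out = n_out,
                 removed = stats::setNames(removed, stage_names),
                 removed_frac = stats::setNames(removed / max(n_in, 1L),
                                                stage_names)),
            class = "dc_qc")
}

#' @export
print.dc_qc <- function(x, ...) {
  cat(sprintf("QC report (%s): %d in -> %d out\n", x$axis, x$n_in, x$n_out))
  for (s in names(x$removed))
    cat(sprintf("  %-14s removed %d (%.2f%%)\n", s, x$removed[[s]],
                100 * x$removed_frac[[s]]))
  invisible(x)
}

#' Filter low-quality cells
#'
#' Removes cells in a fixed order: (1) mitochondrial molecule fraction
#' strictly above `max_mito_frac`, (2) fewer than `min_genes` unique genes
#' detected, (3) total molecules not above `min_molecules`. A
#' `min_molecules` of 0 disables the molecule filter (every cell trivially
#' passes). Each stage's removal count is itemized in the QC report.
#'
#' @param x a [dc_counts()] object.
#' @param max_mito_frac maximum tolerated mitochondrial molecule fraction
#'   (cells strictly above are removed). `NULL` disables the filter.
#' @param min_genes minimum number of unique genes detected (cells with
#'   strictly fewer are removed).
#' @param min_molecules cells must have strictly more total molecules than
#'   this; 0 disables.
#' @param preset optional name in [qc_presets]; explicit arguments override
#'   preset values.
#' @return list with elements `counts` (filtered [dc_counts()]) and `qc`.
#' @export
filter_cells <- function(x, max_mito_frac = 0.20, min_genes = 1000,
                         min_molecules = 0, preset = NULL) {
  stopifnot(inherits(x, "dc_counts"))
  if (!is.null(preset)) {
    p <- qc_presets[[match.arg(preset, names(qc_presets))]]
    if (missing(max_mito_frac)) max_mito_frac <- p$max_mito_frac
    if (missing(min_genes)) min_genes <- p$min_genes
    if (missing(min_molecules)) min_molecules <- p$min_molecules
  }
  if (min_genes < 0 || min_molecules < 0) stop("thresholds must be non-negative")
  counts <- x$counts
  n_in <- nrow(counts)
  keep <- rep(TRUE, n_in)
  totals <- Matrix::rowSums(counts)
  removed <- integer(3)

  if (!is.null(max_mito_frac)) {
    if (is.null(x$mito_mask)) stop("mito_mask required when max_mito_frac is set")
    mito <- if (any(x$mito_mask))
      Matrix::rowSums(counts[, x$mito_mask, drop = FALSE]) else numeric(n_in)
    frac <- ifelse(totals > 0, mito / totals, 0)
    drop1 <- keep & frac > max_mito_frac
    removed[1] <- sum(drop1)
    keep <- keep & !drop1
  }
  n_genes <- Matrix::rowSums(counts > 0)
  drop2 <- keep & n_genes < min_genes
  removed[2] <- sum(drop2)
  keep <- keep & !drop2
  if (min_molecules > 0) {
    drop3 <- keep & totals <= min_molecules
    removed[3] <- sum(drop3)
    keep <- keep & !drop3
  }
  if (!any(keep)) stop("all cells removed by filtering; relax thresholds")
  out <- dc_counts(counts[keep, , drop = FALSE], mito_mask = x$mito_mask)
  qc <- new_qc_report(c("mito_fraction", "min_genes", "min_molecules"),
                      removed, n_in, sum(keep), axis = "cells")
  list(counts = out, qc = qc)
}

#' Filter rarely detected genes
#'
#' Retains genes with nonzero counts in strictly more than `min_cells` cells.
#'
#' @inheritParams filter_cells
#' @param min_cells detection threshold (strict `>`).
#' @return list with `counts` and `qc`.
#' @export
filter_genes <- function(x, min_cells = 10) {
  stopifnot(inherits(x, "dc_counts"), min_cells >= 0)
  n_cells_per_gene <- Matrix::colSums(x$counts > 0)
  keep <- n_cells_per_gene > min_cells
  if (!any(keep)) stop("all genes removed by filtering; relax min_cells")
  out <- dc_counts(x$counts[, keep, drop = FALSE],
                   mito_mask = x$mito_mask[keep])
  qc <- new_qc_report("min_cells", sum(!keep), ncol(x$counts), sum(keep),
                      axis = "genes")
  list(counts = out, qc = qc)
}

#' Library-size normalize and log transform
#'
#' Each cell's counts are divided by its total, multiplied by the median
#' total molecule count across cells, and log2 transformed after adding a
#' pseudocount: `value = log2(count/total * median_total + pseudocount)`.
#'
#' @inheritParams filter_cells
#' @param pseudocount positive pseudocount added before the log (default 0.1).
#' @return a [dc_expr()] with `state = "normalized"`. The median total used
#'   is stored in `attr(, "median_total")` so the transform can be inverted.
#' @export
normalize_counts <- function(x, pseudocount = 0.1) {
  stopifnot(inherits(x, "dc_counts"), pseudocount > 0)
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0))
    stop("cells with zero total counts present; run filter_cells first")
  med <- stats::median(totals)
  scaled <- as.matrix(x$counts / totals * med)
  out <- dc_expr(log2(scaled + pseudocount), state = "normalized",
                 cell_ids = x$cell_ids, gene_ids = x$gene_ids)
  attr(out, "median_total") <- med
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Principal component analysis with a deterministic sign convention
#'
#' PCA of the gene-centered (not scaled) expression matrix via singular value
#' decomposition. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive.
#'
#' @param expr a [dc_expr()] or bare cells x genes matrix.
#' @param n_components number of components to retain.
#' @return object of class `dc_pca` with `scores` (cells x K), `loadings`
#'   (genes x K) and `explained_variance_fraction`.
#' @export
compute_pca <- function(expr, n_components = 20) {
  v <- as_expr_values(expr)
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > min(dim(v)))
    stop("n_components exceeds min(cells, genes)")
  centered <- sweep(v, 2, colMeans(v))
  sv <- svd(centered, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  total_var <- sum(centered^2)
  evf <- if (total_var > 0) sv$d^2 / total_var else rep(0, length(sv$d))
  scores <- sweep(sv$u, 2, d, `*`)
  loadings <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(v)
  rownames(loadings) <- colnames(v)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf[seq_len(n_components)]),
            class = "dc_pca")
}

#' Score a gene signature per cell
#'
#' Averages signature-gene expression per cell. By default each gene is
#' z-scored across cells first so genes of different magnitude contribute
#' comparably; zero-variance genes contribute 0. Signature genes absent from
#' the matrix are ignored with a message.
#'
#' @inheritParams compute_pca
#' @param gene_set character vector of gene ids.
#' @param method `"zscore"` (default) or `"mean"` (raw average).
#' @return named numeric vector of per-cell scores.
#' @export
score_signature <- function(expr, gene_set, method = c("zscore", "mean")) {
  method <- match.arg(method)
  v <- as_expr_values(expr)
  present <- intersect(gene_set, colnames(v))
  if (length(present) == 0) stop("no signature genes present in the matrix")
  missing <- setdiff(gene_set, present)
  if (length(missing) > 0)
    message(length(missing), " signature gene(s) absent and ignored")
  sub <- v[, present, drop = FALSE]
  if (method == "zscore") {
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    sub <- sweep(sub, 2, mu)
    nz <- sdv > 0
    sub[, nz] <- sweep(sub[, nz, drop = FALSE], 2, sdv[nz], `/`)
    sub[, !nz] <- 0
  }
  stats::setNames(rowMeans(sub), rownames(v))
}

#' Gene sets from extreme principal-component loadings
#'
#' For each component, concatenates the `top_n` most-positive and `top_n`
#' most-negative loading genes (2 x `top_n` members), the seeding gene sets
#' used for factor analysis. Ties are broken by gene-id lexicographic order.
#'
#' @param pca a [compute_pca()] result.
#' @param top_n genes taken from each tail (default 30, giving 60 per set).
#' @return named list of character vectors, one per component.
#' @export
pc_gene_sets <- function(pca, top_n = 30) {
  stopifnot(inherits(pca, "dc_pca"))
  genes <- rownames(pca$loadings)
  if (top_n > length(genes) / 2) stop("top_n must be <= genes/2")
  out <- lapply(seq_len(ncol(pca$loadings)), function(j) {
    l <- pca$loadings[, j]
    pos <- genes[order(-l, genes)][seq_len(top_n)]
    neg <- genes[order(l, genes)][seq_len(top_n)]
    c(pos, neg)
  })
  names(out) <- colnames(pca$loadings)
  out
}

#' Regress nuisance factors out of every gene
#'
#' Per gene, ordinary least squares of expression on the factor scores with
#' an intercept; the output is the residual plus the gene mean, so factor-
#' orthogonal genes are unchanged. Zero-variance factors (collinear with the
#' intercept) are dropped with a message; collinearity among the remaining
#' factors is an error.
#'
#' @inheritParams compute_pca
#' @param factor_scores cells x F numeric matrix of factor scores.
#' @return a [dc_expr()] with `state = "residualized"`.
#' @export
regress_out_factors <- function(expr, factor_scores) {
  v <- as_expr_values(expr)
  f <- as.matrix(factor_scores)
  if (!all(is.finite(f))) stop("factor scores must be finite")
  if (nrow(f) != nrow(v)) stop("factor rows must match cells")
  if (is.null(colnames(f))) colnames(f) <- paste0("factor_", seq_len(ncol(f)))
  sdv <- apply(f, 2, stats::sd)
  if (any(sdv == 0)) {
    message("dropping zero-variance factor(s): ",
            paste(colnames(f)[sdv == 0], collapse = ", "))
    f <- f[, sdv > 0, drop = FALSE]
  }
  gene_means <- colMeans(v)
  if (ncol(f) == 0) {
    res <- sweep(v, 2, gene_means)
  } else {
    X <- cbind(`(Intercept)` = 1, f)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("rank-deficient factor matrix; collinear: ",
           paste(bad, collapse = ", "))
    }
    res <- qr.resid(qx, v)
  }
  dc_expr(sweep(res, 2, gene_means, `+`), state = "residualized",
          cell_ids = rownames(v), gene_ids = colnames(v))
}
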