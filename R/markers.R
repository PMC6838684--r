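#' Signed earth mover's distance between two 1-D samples
#'
#' The magnitude is the Wasserstein-1 distance between the empirical
#' distributions: the integral of the absolute difference of the two
#' empirical CDFs over the union of observed values (interval-width
#' weighted). The sign is positive when `median(x) > median(y)`, negative
#' when smaller; when the medians tie the sign of the mean difference is
#' used, and 0 when that also ties.
#'
#' @param x,y non-empty numeric samples.
#' @return a single signed real value.
#' @export
emd_signed <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("samples must be non-empty")
  s <- c(x, y)
  o <- order(s)
  s <- s[o]
  # cumulative F_x - F_y evaluated just after each sorted value; tied values
  # contribute zero-width intervals, so intermediate partial sums are inert
  cdf_diff <- cumsum(rep(c(1 / nx, -1 / ny), c(nx, ny))[o])
  mag <- sum(diff(s) * abs(cdf_diff[-(nx + ny)]))
  dmed <- stats::median(x) - stats::median(y)
  sgn <- if (dmed != 0) sign(dmed) else sign(mean(x) - mean(y))
  sgn * mag
}

#' Area under the ROC curve of a single feature as a classifier
#'
#' Fraction of (target, reference) pairs for which the target value is
#' larger, counting ties as half: the Mann-Whitney U statistic normalized by
#' `n_x * n_y`. Computed by rank statistics in O(n log n).
#'
#' @param x target-group values.
#' @param y reference-group values.
#' @return AUC in \[0, 1\]; values near 1 indicate positive discrimination.
#' @export
auc_score <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

# Vectorized per-gene AUC of target cells vs reference cells.
auc_matrix <- function(values, target_idx, ref_idx) {
  nx <- length(target_idx); ny <- length(ref_idx)
  sub <- values[c(target_idx, ref_idx), , drop = FALSE]
  ranks <- apply(sub, 2, rank)
  (colSums(ranks[seq_len(nx), , drop = FALSE]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Per-gene marker statistics for cluster contrasts
#'
#' For every gene and contrast, computes the signed EMD and the AUC between
#' the target cells and the reference cells. Default contrasts are
#' one-versus-rest for every cluster; a named pair contrast (e.g. one
#' cluster directly against another) can be given instead.
#'
#' @param expr imputed expression ([dc_expr()] with `state = "imputed"`; a
#'   warning is emitted for raw/normalized input, which loses the
#'   discriminative potential of sparsely expressed genes).
#' @param labels cluster label per cell (character/factor, length = cells).
#' @param contrasts `"one_vs_rest"` (default) or a list of
#'   `list(target = , reference = )` label sets; `reference = NULL` means
#'   all remaining cells.
#' @return `data.frame` of class `dc_markers` with columns `gene`,
#'   `contrast`, `signed_emd`, `auc`, `n_target`, `n_reference`, in
#'   deterministic (contrast, gene) order.
#' @export
marker_table <- function(expr, labels, contrasts = "one_vs_rest") {
  v <- as_expr_values(expr)
  if (inherits(expr, "dc_expr") && expr$state != "imputed")
    warning("marker statistics computed on non-imputed expression")
  labels <- as.character(labels)
  if (length(labels) != nrow(v)) stop("labels must cover all cells")
  if (identical(contrasts, "one_vs_rest")) {
    contrasts <- lapply(sort(unique(labels)), function(cl)
      list(target = cl, reference = NULL))
    names(contrasts) <- paste0(sort(unique(labels)), "_vs_rest")
  }
  if (is.null(names(contrasts)))
    names(contrasts) <- vapply(contrasts, function(ct)
      paste0(paste(ct$target, collapse = "+"), "_vs_",
             if (is.null(ct$reference)) "rest" else paste(ct$reference, collapse = "+")),
      character(1))
  rows <- list()
  genes <- colnames(v)
  gene_order <- order(genes)
  for (cname in names(contrasts)) {
    ct <- contrasts[[cname]]
    tgt <- which(labels %in% ct$target)
    ref <- if (is.null(ct$reference)) which(!(labels %in% ct$target)) else
      which(labels %in% ct$reference)
    if (length(tgt) < 2 || length(ref) < 2) {
      warning("contrast '", cname, "' skipped: fewer than 2 cells in a group")
      next
    }
    emd <- vapply(seq_along(genes), function(g)
      emd_signed(v[tgt, g], v[ref, g]), numeric(1))
    auc <- auc_matrix(v, tgt, ref)
    rows[[cname]] <- data.frame(
      gene = genes[gene_order], contrast = cname,
      signed_emd = emd[gene_order], auc = unname(auc)[gene_order],
      n_target = length(tgt), n_reference = length(ref),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(gene = character(0), contrast = character(0),
                      signed_emd = numeric(0), auc = numeric(0),
                      n_target = integer(0), n_reference = integer(0))
    class(out) <- c("dc_markers", "data.frame")
    return(out)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$contrast, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dc_markers", "data.frame")
  out
}

#' Select discriminative markers by joint AUC and EMD thresholds
#'
#' Retains genes whose AUC reaches `auc_min` (or `1 - auc_min` for negative
#' discriminators when `two_sided`) and whose signed EMD lies outside
#' `mu +/- multiplier * sigma`, where `mu` and `sigma` are the mean and SD
#' of signed EMD across all genes of that contrast (a robust median/MAD
#' variant is available).
#'
#' @param table a [marker_table()] result.
#' @param auc_min AUC threshold in (0.5, 1\]; default 0.99.
#' @param emd_sd_multiplier number of EMD standard deviations (default 3;
#'   the stricter published alternative is 4).
#' @param two_sided also admit negative discriminators (default TRUE).
#' @param robust use median/MAD in place of mean/SD.
#' @return the selected subset of `table`, with an added logical column
#'   `positive` (direction of the marker).
#' @export
select_markers <- function(table, auc_min = 0.99, emd_sd_multiplier = 3,
                           two_sided = TRUE, robust = FALSE) {
  stopifnot(auc_min >= 0.5, auc_min <= 1, emd_sd_multiplier > 0)
  keep <- logical(nrow(table))
  positive <- logical(nrow(table))
  for (cname in unique(table$contrast)) {
    i <- table$contrast == cname
    e <- table$signed_emd[i]
    mu <- if (robust) stats::median(e) else mean(e)
    sig <- if (robust) stats::mad(e) else stats::sd(e)
    if (!is.finite(sig) || sig == 0)
      stop("degenerate EMD spread (sigma = 0) in contrast '", cname, "'")
    hi <- e > mu + emd_sd_multiplier * sig
    lo <- e < mu - emd_sd_multiplier * sig
    up <- table$auc[i] >= auc_min
    dn <- two_sided & table$auc[i] <= 1 - auc_min
    keep[i] <- (up | dn) & (hi | (two_sided & lo))
    positive[i] <- hi
  }
  out <- table[keep, , drop = FALSE]
  out$positive <- positive[keep]
  rownames(out) <- NULL
  out
}

#' Cell-number rescaling diagnostic for EMD
#'
#' Recomputes each gene's signed EMD with balanced subsampling to the
#' smaller group size (averaged over `n_reps` seeded repetitions) and
#' reports it alongside the original, plus the Spearman rank correlation
#' between the two — a check that group-size imbalance does not drive the
#' EMD ranking.
#'
#' @inheritParams marker_table
#' @param target cluster label(s) defining the target group.
#' @param reference label(s) for the reference group; `NULL` = all others.
#' @param n_reps subsampling repetitions (default 25).
#' @param seed RNG seed for the subsampling.
#' @return `data.frame(gene, signed_emd, signed_emd_balanced)` with the rank
#'   correlation in `attr(, "rank_correlation")`.
#' @export
emd_rescale_diagnostic <- function(expr, labels, target, reference = NULL,
                                   n_reps = 25, seed = 1) {
  v <- as_expr_values(expr)
  labels <- as.character(labels)
  tgt <- which(labels %in% target)
  ref <- if (is.null(reference)) which(!(labels %in% target)) else
    which(labels %in% reference)
  if (length(tgt) < 2 || length(ref) < 2) stop("need >= 2 cells per group")
  genes <- colnames(v)
  orig <- vapply(seq_along(genes), function(g)
    emd_signed(v[tgt, g], v[ref, g]), numeric(1))
  m <- min(length(tgt), length(ref))
  acc <- numeric(length(genes))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      ts <- sample(tgt, m)
      rs <- sample(ref, m)
      acc <- acc + vapply(seq_along(genes), function(g)
        emd_signed(v[ts, g], v[rs, g]), numeric(1))
    }
  })
  bal <- acc / n_reps
  out <- data.frame(gene = genes, signed_emd = orig,
                    signed_emd_balanced = bal, stringsAsFactors = FALSE)
  attr(out, "rank_correlation") <- if (length(genes) > 1)
    stats::cor(orig, bal, method = "spearman") else 1
  out
}
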