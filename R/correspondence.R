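#' Per-cluster centroid expression profiles
#'
#' Mean expression per cluster per gene, optionally standardized per gene
#' across clusters (z-score with the sample SD; zero-variance genes map
#' to 0).
#'
#' @param expr a [dc_expr()] or cells x genes matrix.
#' @param labels per-cell cluster labels (every cluster non-empty).
#' @param zscore standardize per gene across clusters (default FALSE).
#' @return clusters x genes matrix.
#' @export
centroid_profiles <- function(expr, labels, zscore = FALSE) {
  v <- as_expr_values(expr)
  labels <- as.character(labels)
  if (length(labels) != nrow(v)) stop("labels must cover all cells")
  lev <- sort(unique(labels))
  cent <- t(vapply(lev, function(cl)
    colMeans(v[labels == cl, , drop = FALSE]), numeric(ncol(v))))
  rownames(cent) <- lev
  colnames(cent) <- colnames(v)
  if (zscore) cent <- zscore_cols(cent)
  cent
}

#' Read a two-column ortholog map
#'
#' @param path TSV with two columns (species-A gene id, species-B gene id);
#'   a header line is auto-detected via the column names `gene_a`/`gene_b`.
#' @return `data.frame(gene_a, gene_b)`.
#' @export
read_ortholog_map <- function(path) {
  first <- utils::read.delim(path, nrows = 1, header = FALSE,
                             stringsAsFactors = FALSE)
  header <- identical(tolower(as.character(first[1, 1])), "gene_a")
  m <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  m <- m[, 1:2]
  names(m) <- c("gene_a", "gene_b")
  if (any(is.na(m)) || any(m == "")) stop("ortholog map contains null ids")
  m
}

#' Reduce a many-to-many ortholog map to one-to-one pairs
#'
#' Pairs in which both genes map uniquely are kept as they stand; for genes
#' with several partners the partner with the highest total expression is
#' kept when expression totals are supplied, otherwise the lexicographically
#' first partner (the applied rule is logged via `message`).
#'
#' @param map `data.frame(gene_a, gene_b)`.
#' @param totals_a,totals_b optional named numeric vectors of per-gene total
#'   expression used to rank competing partners.
#' @return reduced one-to-one `data.frame(gene_a, gene_b)`.
#' @export
reduce_orthologs <- function(map, totals_a = NULL, totals_b = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(map)))
  score <- function(genes, totals) {
    if (is.null(totals)) return(rep(0, length(genes)))
    s <- totals[genes]
    s[is.na(s)] <- -Inf
    as.numeric(s)
  }
  m <- map
  m$s <- score(m$gene_b, totals_b) + score(m$gene_a, totals_a)
  m <- m[order(m$gene_a, -m$s, m$gene_b), ]
  m <- m[!duplicated(m$gene_a), ]
  m <- m[order(m$gene_b, -m$s, m$gene_a), ]
  m <- m[!duplicated(m$gene_b), ]
  message(sprintf("ortholog reduction: %d pairs -> %d one-to-one (%s)",
                  nrow(map), nrow(m),
                  if (is.null(totals_a) && is.null(totals_b))
                    "lexicographic rule" else "highest-total-expression rule"))
  rownames(m) <- NULL
  m[, c("gene_a", "gene_b")]
}

#' Pearson correlation between two sets of centroid profiles
#'
#' Each matrix is standardized per gene across its clusters, then the
#' Pearson correlation over the shared gene universe is computed for every
#' cluster pair. When an ortholog map is given, genes of `b` are first
#' translated to `a`'s namespace (after one-to-one reduction) and the
#' universe is the orthologous intersection.
#'
#' @param a,b clusters x genes centroid matrices (see [centroid_profiles()]).
#' @param ortholog_map optional `data.frame(gene_a, gene_b)`.
#' @param zscore standardize per gene across clusters first (default TRUE,
#'   the cross-dataset convention; set FALSE if inputs are pre-standardized).
#' @return clusters_a x clusters_b correlation matrix with the shared-gene
#'   count in `attr(, "n_genes")`.
#' @export
correlate_profiles <- function(a, b, ortholog_map = NULL, zscore = TRUE) {
  if (!is.null(ortholog_map)) {
    m <- reduce_orthologs(ortholog_map,
                          totals_a = colSums(a)[unique(ortholog_map$gene_a)],
                          totals_b = colSums(b)[unique(ortholog_map$gene_b)])
    m <- m[m$gene_a %in% colnames(a) & m$gene_b %in% colnames(b), ]
    a <- a[, m$gene_a, drop = FALSE]
    b <- b[, m$gene_b, drop = FALSE]
    colnames(b) <- m$gene_a
  }
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  if (zscore) { a <- zscore_cols(a); b <- zscore_cols(b) }
  out <- stats::cor(t(a), t(b))
  attr(out, "n_genes") <- length(shared)
  out
}

#' Elastic-net one-vs-rest cluster signature coefficients
#'
#' Genes with total count over all cells strictly above `total_count_min`
#' are retained; counts are library-normalized to the median total and
#' log2(x + 1) transformed (this procedure's own transform). Per cluster, a
#' penalized binomial regression (cell-in-cluster vs rest) is fitted over a
#' penalty path with stratified cross-validation selecting the penalty that
#' maximizes held-out classification AUC; the gene coefficients at that
#' penalty are returned with the achieved AUC.
#'
#' @param x a [dc_counts()] object.
#' @param labels per-cell cluster labels (>= 2 clusters).
#' @param total_count_min gene total-count filter, strict `>` (default 300).
#' @param alpha elastic-net mixing parameter (default 0.99).
#' @param n_folds cross-validation folds (default 10); every cluster must
#'   have at least `n_folds` cells.
#' @param seed RNG seed for fold assignment.
#' @param penalty `"min"` (default; the AUC-maximizing penalty) or `"1se"`
#'   (the most regularized penalty within one standard error of it).
#' @return object of class `dc_signature`: per-cluster list with
#'   `coefficients` (named, genes only, at the selected penalty),
#'   `coefficients_1se` (the one-SE alternative, always reported), `cv_auc`,
#'   `lambda`, `sparsity_fraction`; plus the `genes` universe used.
#' @export
signature_coefficients <- function(x, labels, total_count_min = 300,
                                   alpha = 0.99, n_folds = 10, seed = 1,
                                   penalty = c("min", "1se")) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(x, "dc_counts"))
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need at least two clusters")
  if (any(table(labels) < n_folds))
    stop("every cluster needs at least n_folds cells")
  totals_g <- Matrix::colSums(x$counts)
  keep <- totals_g > total_count_min
  if (sum(keep) < 2) stop("fewer than 2 genes pass the total-count filter")
  counts <- x$counts[, keep, drop = FALSE]
  totals_c <- Matrix::rowSums(x$counts)
  med <- stats::median(totals_c)
  xmat <- log2(as.matrix(counts / totals_c * med) + 1)
  fits <- list()
  for (cl in lev) {
    yv <- as.integer(labels == cl)
    foldid <- integer(length(yv))
    with_seed(seed, {
      for (g in c(0L, 1L)) {
        i <- which(yv == g)
        foldid[i] <- sample(rep_len(seq_len(n_folds), length(i)))
      }
    })
    cv <- glmnet::cv.glmnet(xmat, yv, family = "binomial", alpha = alpha,
                            foldid = foldid, type.measure = "auc")
    co <- as.numeric(stats::coef(cv, s = cv[[paste0("lambda.", penalty)]]))[-1]
    names(co) <- colnames(xmat)
    co_1se <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]
    names(co_1se) <- colnames(xmat)
    fits[[cl]] <- list(coefficients = co,
                       coefficients_1se = co_1se,
                       cv_auc = max(cv$cvm),
                       lambda = cv[[paste0("lambda.", penalty)]],
                       sparsity_fraction = mean(co == 0))
  }
  structure(list(fits = fits, genes = colnames(xmat), alpha = alpha),
            class = "dc_signature")
}

#' Correlate cluster signature coefficients with bulk profiles
#'
#' Pearson correlation between each cluster's coefficient vector and each
#' bulk sample's normalized expression over the genes present in both.
#'
#' @param sig a [signature_coefficients()] result.
#' @param bulk samples x genes matrix of library-size-normalized bulk
#'   expression.
#' @param zscore_columns z-score each bulk-sample column of the output for
#'   display parity (default FALSE).
#' @return clusters x samples correlation matrix.
#' @export
bulk_similarity <- function(sig, bulk, zscore_columns = FALSE) {
  stopifnot(inherits(sig, "dc_signature"))
  bulk <- as.matrix(bulk)
  shared <- intersect(sig$genes, colnames(bulk))
  if (length(shared) < 3) stop("fewer than 3 genes shared with the bulk table")
  cmat <- vapply(sig$fits, function(f) f$coefficients[shared],
                 numeric(length(shared)))
  out <- stats::cor(cmat, t(bulk[, shared, drop = FALSE]))
  dimnames(out) <- list(names(sig$fits), rownames(bulk))
  if (zscore_columns) out <- zscore_cols(out)
  attr(out, "n_genes") <- length(shared)
  out
}

#' Core signature genes from per-tissue differential tables
#'
#' Per tissue, genes passing `FDR < fdr_max`, `|log2FC| > lfc_min` (strict)
#' and `mean_count >= mean_count_min` are split by fold-change sign; the
#' cross-tissue intersection is reported per direction.
#'
#' @param tables named list of `data.frame`s sharing a gene universe, each
#'   with columns `gene`, `log2FC`, `FDR`, `mean_count`.
#' @param fdr_max,lfc_min,mean_count_min thresholds (defaults 0.01, 1.5, 50).
#' @return list with `per_table` (up/down sets per tissue), `overlap_up`,
#'   `overlap_down`.
#' @export
core_signature <- function(tables, fdr_max = 0.01, lfc_min = 1.5,
                           mean_count_min = 50) {
  need <- c("gene", "log2FC", "FDR", "mean_count")
  per <- lapply(tables, function(tb) {
    if (!all(need %in% names(tb)))
      stop("table missing required columns: ",
           paste(setdiff(need, names(tb)), collapse = ", "))
    pass <- tb$FDR < fdr_max & abs(tb$log2FC) > lfc_min &
      tb$mean_count >= mean_count_min
    list(up = tb$gene[pass & tb$log2FC > 0],
         down = tb$gene[pass & tb$log2FC < 0])
  })
  list(per_table = per,
       overlap_up = Reduce(intersect, lapply(per, `[[`, "up")),
       overlap_down = Reduce(intersect, lapply(per, `[[`, "down")))
}

# Vectorized classical one-way ANOVA F and p per column of `v`.
anova_f <- function(v, labels) {
  labels <- factor(labels)
  keep_cl <- names(which(table(labels) >= 2))
  if (length(keep_cl) < length(levels(labels)))
    warning("cluster(s) with < 2 cells excluded from ANOVA: ",
            paste(setdiff(levels(labels), keep_cl), collapse = ", "))
  sel <- labels %in% keep_cl
  v <- v[sel, , drop = FALSE]
  labels <- droplevels(labels[sel])
  k <- nlevels(labels); n <- nrow(v)
  if (k < 2) stop("need at least two clusters with >= 2 cells")
  grand <- colMeans(v)
  ssb <- numeric(ncol(v)); ssw <- numeric(ncol(v))
  for (cl in levels(labels)) {
    i <- labels == cl
    mu <- colMeans(v[i, , drop = FALSE])
    ssb <- ssb + sum(i) * (mu - grand)^2
    ssw <- ssw + colSums(sweep(v[i, , drop = FALSE], 2, mu)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw == 0 & ssb == 0] <- 0
  f[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(f = f, p = p)
}

#' Select cluster-variable transcription factors by one-way ANOVA
#'
#' Per species, a classical one-way ANOVA F-test of each TF's expression
#' across clusters, Benjamini-Hochberg adjusted, selected at
#' `FDR < fdr_max`. An expression pre-filter (mean linear-scale expression
#' above `min_mean`) is applied first when `min_mean` is given. When two
#' species are supplied the final list is the intersection through the
#' ortholog map.
#'
#' @param expr,labels expression and cluster labels for species A.
#' @param tf_genes candidate TF gene ids (species A namespace).
#' @param expr_b,labels_b optional second species.
#' @param ortholog_map required with a second species
#'   (`data.frame(gene_a, gene_b)`).
#' @param fdr_max FDR threshold (default 1e-5).
#' @param min_mean optional mean-expression pre-filter on `2^expr` scale.
#' @return list with per-species `data.frame(gene, F, p, fdr, selected)` and
#'   `selected` (intersection in species-A ids when both species given).
#' @export
select_variable_tfs <- function(expr, labels, tf_genes, expr_b = NULL,
                                labels_b = NULL, ortholog_map = NULL,
                                fdr_max = 1e-5, min_mean = NULL) {
  if (length(tf_genes) == 0) stop("tf_genes must be non-empty")
  one_species <- function(e, lab, tfs) {
    v <- as_expr_values(e)
    tfs <- intersect(tfs, colnames(v))
    if (length(tfs) == 0) stop("no candidate TFs present in the matrix")
    if (!is.null(min_mean))
      tfs <- tfs[colMeans(2^v[, tfs, drop = FALSE]) > min_mean]
    res <- anova_f(v[, tfs, drop = FALSE], lab)
    fdr <- bh_adjust(res$p)
    data.frame(gene = tfs, F = res$f, p = res$p, fdr = fdr,
               selected = fdr < fdr_max, stringsAsFactors = FALSE)
  }
  res_a <- one_species(expr, labels, tf_genes)
  if (is.null(expr_b))
    return(list(species_a = res_a, selected = res_a$gene[res_a$selected]))
  if (is.null(ortholog_map)) stop("ortholog_map required with two species")
  m <- reduce_orthologs(ortholog_map)
  tf_b <- m$gene_b[m$gene_a %in% tf_genes]
  res_b <- one_species(expr_b, labels_b, tf_b)
  sel_b_as_a <- m$gene_a[match(res_b$gene[res_b$selected], m$gene_b)]
  selected <- intersect(res_a$gene[res_a$selected], sel_b_as_a)
  list(species_a = res_a, species_b = res_b, selected = selected)
}

#' Cross-species transcription-factor program overlap
#'
#' TF expression profiles (TFs as observations) are z-scored and clustered
#' within each species with a cosine-metric k-NN community clusterer; the
#' overlap matrix counts orthologous TFs shared by every (A-cluster,
#' B-cluster) pair. Matrix entries sum to the number of shared selected TFs.
#'
#' @param prof_a,prof_b TFs x features matrices (e.g. imputed per-cluster or
#'   per-cell profiles), rows named by TF gene id.
#' @param selected_tfs TFs to use, in species-A ids.
#' @param ortholog_map `data.frame(gene_a, gene_b)` (one-to-one after
#'   reduction); identity map assumed when NULL (same namespace).
#' @param k clusterer neighborhood size (default 10).
#' @param seed clusterer seed.
#' @return object of class `dc_tfprograms`: `clusters_a`, `clusters_b`
#'   (named label vectors), `overlap` (A-clusters x B-clusters counts).
#' @export
tf_program_overlap <- function(prof_a, prof_b, selected_tfs,
                               ortholog_map = NULL, k = 10, seed = 1) {
  if (is.null(ortholog_map))
    ortholog_map <- data.frame(gene_a = selected_tfs, gene_b = selected_tfs)
  m <- reduce_orthologs(ortholog_map)
  m <- m[m$gene_a %in% selected_tfs & m$gene_a %in% rownames(prof_a) &
           m$gene_b %in% rownames(prof_b), ]
  if (nrow(m) <= k) stop("fewer selected TFs than k; use a smaller k")
  cluster_profiles <- function(p) {
    z <- t(zscore_cols(t(p)))          # z-score each TF profile
    # cosine distance via unit-norm rows + Euclidean embedding
    nrm <- sqrt(rowSums(z^2))
    nrm[nrm == 0] <- 1
    default_clusterer(z / nrm, k = k, seed = seed)
  }
  ca <- stats::setNames(cluster_profiles(prof_a[m$gene_a, , drop = FALSE]),
                        m$gene_a)
  cb <- stats::setNames(cluster_profiles(prof_b[m$gene_b, , drop = FALSE]),
                        m$gene_b)
  overlap <- table(A = ca, B = cb[match(m$gene_b, names(cb))])
  structure(list(clusters_a = ca, clusters_b = cb,
                 overlap = unclass(overlap), n_shared = nrow(m)),
            class = "dc_tfprograms")
}

#' Kolmogorov-Smirnov shift test of a gene signature
#'
#' Two-sided two-sample KS test comparing the log2 fold changes of the
#' signature genes with those of the full background (all expressed genes),
#' with the empirical CDF step curves returned for plotting.
#'
#' @param background_log2fc named numeric vector (gene -> log2FC) for all
#'   expressed genes.
#' @param signature_genes gene ids; at least 3 must be present in the
#'   background.
#' @return list `D`, `p_value`, `cdf_background`, `cdf_signature` (each a
#'   two-column `data.frame(value, cdf)`), `n_signature`.
#' @export
signature_shift_test <- function(background_log2fc, signature_genes) {
  sig <- background_log2fc[intersect(signature_genes, names(background_log2fc))]
  if (length(sig) < 3) stop("fewer than 3 signature genes overlap the background")
  kt <- suppressWarnings(stats::ks.test(sig, background_log2fc,
                                        alternative = "two.sided"))
  curve <- function(v) {
    s <- sort(v)
    data.frame(value = s, cdf = seq_along(s) / length(s))
  }
  list(D = unname(kt$statistic), p_value = kt$p.value,
       cdf_background = curve(background_log2fc), cdf_signature = curve(sig),
       n_signature = length(sig))
}
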