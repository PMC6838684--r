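toy_counts <- function(mat, genes = NULL, mito = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(mat)))
  dc_counts(mat, cell_ids = paste0("c", seq_len(nrow(mat))),
            gene_ids = genes, mito_mask = mito)
}

test_that("cell filters apply the strict thresholds in order", {
  # 5 cells with unique-gene counts 2,3,4,5,6 over 6 genes; one mito gene
  mat <- matrix(0, 5, 6)
  for (i in 1:5) mat[i, seq_len(i + 1)] <- 5
  x <- toy_counts(mat, genes = c("mt-1", paste0("g", 1:5)))
  # mito fractions are 1/2, 1/3, 1/4, 1/5, 1/6: strictly above 20% for the
  # first three cells only (exactly 20% is retained)
  r <- filter_cells(x, max_mito_frac = 0.2, min_genes = 3, min_molecules = 0)
  expect_equal(r$qc$removed[["mito_fraction"]], 3L)
  expect_error(filter_cells(x, max_mito_frac = 0.0, min_genes = 0),
               "all cells removed")

  # unique-gene filter is strictly "<": 999 removed, 1000 kept
  genes_per_cell <- c(800, 999, 1000, 1200, 1500)
  big <- matrix(0, 5, 1500)
  for (i in 1:5) big[i, seq_len(genes_per_cell[i])] <- 1
  xb <- toy_counts(big)
  rb <- filter_cells(xb, max_mito_frac = NULL, min_genes = 1000)
  expect_equal(length(rb$counts$cell_ids), 3L)
  expect_equal(rb$qc$removed[["min_genes"]], 2L)

  # all-zero thresholds are the identity on cells (no mito genes expressed)
  x0 <- toy_counts(matrix(1:12, 3, 4))
  r0 <- filter_cells(x0, max_mito_frac = 0, min_genes = 0, min_molecules = 0)
  expect_equal(r0$counts$cell_ids, x0$cell_ids)

  # molecule filter is strict ">"
  xm <- toy_counts(rbind(rep(2, 4), rep(3, 4)))
  rm_ <- filter_cells(xm, max_mito_frac = NULL, min_genes = 0,
                      min_molecules = 8)
  expect_equal(length(rm_$counts$cell_ids), 1L)
})

test_that("cell filtering is idempotent and presets resolve", {
  set.seed(1)
  x <- toy_counts(matrix(rpois(600, 3), 20, 30))
  r1 <- filter_cells(x, max_mito_frac = NULL, min_genes = 25)
  r2 <- filter_cells(r1$counts, max_mito_frac = NULL, min_genes = 25)
  expect_identical(r1$counts$cell_ids, r2$counts$cell_ids)
  expect_equal(r2$qc$removed[["min_genes"]], 0L)
  expect_equal(qc_presets$mouse_spleen$min_genes, 1000)
  expect_equal(qc_presets$human_spleen$min_molecules, 6000)
})

test_that("gene filter keeps genes detected in strictly more than min_cells", {
  # genes nonzero in 0, 5, 11, 20 cells
  mat <- matrix(0, 25, 4)
  mat[seq_len(5), 2] <- 1
  mat[seq_len(11), 3] <- 1
  mat[seq_len(20), 4] <- 1
  mat[, 1] <- 0
  mat[1, 1] <- 0
  x <- toy_counts(mat)
  x$counts[1, 1] <- 0
  r <- filter_genes(x, min_cells = 10)
  expect_equal(r$counts$gene_ids, c("g3", "g4"))
  # gene in exactly 10 cells is removed
  mat2 <- matrix(0, 12, 2)
  mat2[1:10, 1] <- 1; mat2[1:11, 2] <- 1
  r2 <- filter_genes(toy_counts(mat2), min_cells = 10)
  expect_equal(r2$counts$gene_ids, "g2")
  # min_cells = 0 keeps every expressed gene
  r3 <- filter_genes(toy_counts(matrix(1, 3, 3)), min_cells = 0)
  expect_equal(length(r3$counts$gene_ids), 3L)
  expect_error(filter_genes(toy_counts(matrix(0L, 3, 2) + 0), 10),
               "all genes removed")
})

test_that("normalization matches the log2 median-scaling formula and inverts", {
  x <- toy_counts(matrix(c(10, 90, 10, 290), 2, 2, byrow = TRUE))
  e <- normalize_counts(x, pseudocount = 0.1)
  expect_equal(2^e$values - 0.1,
               matrix(c(20, 180, 20 / 3, 580 / 3), 2, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero counts floor at log2(pseudocount)
  x2 <- toy_counts(matrix(c(0, 5, 3, 2), 2, 2))
  e2 <- normalize_counts(x2)
  expect_equal(e2$values[1, 1], log2(0.1))
  # round trip: counts recoverable from totals and the median factor
  totals <- Matrix::rowSums(x$counts)
  rec <- (2^e$values - 0.1) / attr(e, "median_total") * totals
  expect_equal(rec, as.matrix(x$counts), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(normalize_counts(toy_counts(rbind(c(0, 0), c(1, 2)))),
               "zero total")
})

test_that("PCA reproduces an eigendecomposition oracle with fixed signs", {
  set.seed(7)
  m <- matrix(rnorm(50 * 20), 50, 20)
  p <- compute_pca(m, 5)
  centered <- sweep(m, 2, colMeans(m))
  eg <- eigen(crossprod(centered), symmetric = TRUE)   # independent route
  for (j in 1:5) {
    v <- eg$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(p$loadings[, j], v, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(p$scores[, j], as.numeric(centered %*% v), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_true(all(diff(p$explained_variance_fraction) <= 1e-12))
  # rank-1 matrix: first component explains everything
  r1 <- compute_pca(outer(rnorm(10), rnorm(4)), 2)
  expect_equal(r1$explained_variance_fraction[1], 1, tolerance = 1e-10)
  expect_lt(r1$explained_variance_fraction[2], 1e-10)
  # constant matrix: all zero variance
  expect_equal(compute_pca(matrix(3, 8, 4), 2)$explained_variance_fraction,
               c(0, 0))
})

test_that("signature scoring z-scores genes and tolerates absent ones", {
  v <- cbind(a = c(0, 0, 4, 4), b = c(1, 1, 1, 1), c = rnorm(4))
  e <- dc_expr(v, "normalized", cell_ids = paste0("c", 1:4))
  s1 <- score_signature(e, "a")
  expect_equal(unname(s1), as.numeric(scale(v[, "a"])))
  # zero-variance gene contributes 0
  s2 <- score_signature(e, c("a", "b"))
  expect_equal(unname(s2), as.numeric(scale(v[, "a"])) / 2)
  expect_message(score_signature(e, c("a", "zz")), "absent")
  expect_error(score_signature(e, "nope"), "no signature genes")
  # identical cells give all-zero scores
  const <- dc_expr(matrix(2, 5, 3), "normalized")
  expect_equal(unname(score_signature(const, colnames(const$values))),
               rep(0, 5))
})

test_that("pc_gene_sets takes both loading tails with lexicographic ties", {
  loadings <- c(3, 2, 1, -1, -2, -3)
  m <- outer(rnorm(30), loadings)
  colnames(m) <- paste0("g", 1:6)
  p <- compute_pca(m, 1)
  s <- pc_gene_sets(p, top_n = 2)
  expect_setequal(s[[1]], c("g1", "g2", "g5", "g6"))
  expect_length(s[[1]], 4)
  # tie-break: equal loadings ordered by gene id
  m2 <- outer(rnorm(30), c(1, 1, -1, -1, 0, 0))
  colnames(m2) <- c("gb", "ga", "gd", "gc", "ge", "gf")
  s2 <- pc_gene_sets(compute_pca(m2, 1), top_n = 1)
  expect_equal(sort(s2[[1]]), c("ga", "gc"))
  expect_error(pc_gene_sets(p, top_n = 4), "top_n")
})

test_that("factor residualization removes fitted structure only", {
  set.seed(11)
  n <- 500
  f1 <- rnorm(n)
  g_signal <- 2 * f1 + rnorm(n, sd = 0.1)
  g_orth <- rnorm(n)
  g_equal <- f1
  v <- cbind(sig = g_signal, orth = g_orth, eq = g_equal)
  e <- dc_expr(v, "normalized")
  r <- regress_out_factors(e, cbind(f1 = f1))
  expect_equal(r$state, "residualized")
  # fitted gene collapses to its mean
  expect_equal(unname(r$values[, "eq"]), rep(mean(g_equal), n),
               tolerance = 1e-10)
  # residual variance of the noisy gene approaches sigma^2 (within 20%)
  expect_equal(var(r$values[, "sig"]), 0.01, tolerance = 0.2)
  # agreement with lm() residuals as an independent route
  expect_equal(unname(r$values[, "orth"]),
               unname(resid(lm(g_orth ~ f1)) + mean(g_orth)),
               tolerance = 1e-8)
  # a gene exactly orthogonal to intercept and factors is unchanged
  go <- unname(resid(lm(rnorm(n) ~ f1)))
  ro <- regress_out_factors(dc_expr(cbind(go = go), "normalized"),
                            cbind(f1 = f1))
  expect_lt(max(abs(ro$values[, "go"] - go)), 1e-8)
  # zero-variance factors are dropped -> identity
  expect_message(r0 <- regress_out_factors(e, cbind(z = rep(1, n))),
                 "zero-variance")
  expect_equal(r0$values, e$values, tolerance = 1e-10)
  # collinear factors are an error naming the culprit
  expect_error(regress_out_factors(e, cbind(a = f1, b = 2 * f1)),
               "rank-deficient")
})
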