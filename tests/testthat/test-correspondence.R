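test_that("centroid profiles average per cluster with the documented z-score", {
  v <- rbind(matrix(0, 4, 3), matrix(2, 4, 3))
  colnames(v) <- paste0("g", 1:3)
  lab <- rep(c("a", "b"), each = 4)
  cent <- centroid_profiles(v, lab)
  expect_equal(cent, rbind(a = rep(0, 3), b = rep(2, 3)), ignore_attr = TRUE)
  # sample-SD convention: values 0 and 2 z-score to -/+ 1/sqrt(2)
  cz <- centroid_profiles(v, lab, zscore = TRUE)
  expect_equal(cz[, 1], c(a = -1 / sqrt(2), b = 1 / sqrt(2)))
  # single cluster: centroid is the global mean, z-scores all zero
  c1 <- centroid_profiles(v, rep("only", 8), zscore = TRUE)
  expect_equal(unname(c1[1, ]), rep(0, 3))
  # a cluster of one cell equals that cell
  v2 <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("g", 1:3)))
  cs <- centroid_profiles(v2, c("solo", "rest", "rest", "rest"))
  expect_equal(unname(cs["solo", ]), unname(v2[1, ]))
})

test_that("profile correlation respects the shared-gene universe and orthologs", {
  cent <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8, 4, 3, 2, 1), 3, 4, byrow = TRUE,
                 dimnames = list(c("c1", "c2", "c3"), paste0("g", 1:4)))
  cc <- correlate_profiles(cent, cent, zscore = FALSE)
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc["c1", "c2"], 1)         # perfectly linear pair
  expect_equal(cc["c1", "c3"], -1)        # negation
  expect_equal(attr(cc, "n_genes"), 4)
  # ortholog translation: same profiles under renamed genes
  b <- cent
  colnames(b) <- paste0("h", 1:4)
  map <- data.frame(gene_a = paste0("g", 1:4), gene_b = paste0("h", 1:4))
  cb <- suppressMessages(correlate_profiles(cent, b, ortholog_map = map,
                                            zscore = FALSE))
  expect_equal(diag(cb), rep(1, 3), ignore_attr = TRUE)
  expect_error(correlate_profiles(cent[, 1:2], cent[, 1:2]),
               "fewer than 3")
  # invariant to per-gene affine rescaling after z-scoring
  resc <- sweep(sweep(cent, 2, c(2, 3, 0.5, 10), `*`), 2, c(1, -2, 0, 5), `+`)
  expect_equal(correlate_profiles(cent, cent, zscore = TRUE),
               correlate_profiles(cent, resc, zscore = TRUE),
               tolerance = 1e-12)
})

test_that("ortholog reduction yields one-to-one pairs by the stated rule", {
  map <- data.frame(gene_a = c("a1", "a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3", "b3"))
  red <- suppressMessages(reduce_orthologs(map))
  expect_false(anyDuplicated(red$gene_a) > 0)
  expect_false(anyDuplicated(red$gene_b) > 0)
  # expression totals break the competition toward the expressed partner
  red2 <- suppressMessages(
    reduce_orthologs(map, totals_b = c(b1 = 1, b2 = 100, b3 = 5)))
  expect_true("b2" %in% red2$gene_b)
  expect_false("b1" %in% red2$gene_b)
})

test_that("elastic-net signatures separate planted clusters and stay null on noise", {
  sim <- make_sc_counts(n_cells = 240, n_genes = 200, n_subsets = 2,
                        n_markers = 4, marker_effect = 2.5,
                        lib_median = 1200, dropout = 0.3, seed = 41)
  lab <- sim$truth$labels
  sig <- signature_coefficients(sim$counts, lab, total_count_min = 50,
                                n_folds = 5, seed = 1)
  expect_gte(sig$fits$subset_1$cv_auc, 0.99)
  # the recovered support is pure: every selected gene is a planted marker
  # (the L1 path keeps a minimal separating subset when AUC saturates)
  co <- sig$fits$subset_1$coefficients
  support <- names(co)[co != 0]
  expect_gt(length(support), 0)
  expect_true(all(support %in% sim$truth$markers$gene))
  # direction: subset_1 markers enter positively, subset_2 markers negatively
  m1 <- sim$truth$markers$gene[sim$truth$markers$subset == "subset_1"]
  expect_true(all(co[setdiff(support, m1)] < 0))
  expect_true(all(co[intersect(support, m1)] > 0))
  # random labels: held-out AUC near chance and far below the separable fit
  rnd <- with_seed_test(42, sample(lab))
  sig0 <- signature_coefficients(sim$counts, rnd, total_count_min = 50,
                                 n_folds = 5, seed = 1)
  expect_lt(abs(sig0$fits$subset_1$cv_auc - 0.5), 0.1)
  expect_gt(sig$fits$subset_1$cv_auc - sig0$fits$subset_1$cv_auc, 0.4)
  expect_error(signature_coefficients(sim$counts, rep("one", 240)),
               "two clusters")
})

test_that("a single informative gene earns the dominant positive coefficient", {
  set.seed(49)
  n <- 200
  lab <- rep(c("A", "B"), each = n / 2)
  counts <- matrix(rpois(n * 40, 5), n, 40)
  counts[lab == "A", 7] <- rpois(n / 2, 40)      # the one informative gene
  colnames(counts) <- paste0("g", 1:40)
  x <- dc_counts(counts)
  sig <- signature_coefficients(x, lab, total_count_min = 0, n_folds = 5,
                                seed = 1)
  co <- sig$fits$A$coefficients
  expect_gt(co["g7"], 0)
  expect_equal(names(which.max(abs(co))), "g7")
  expect_gte(sig$fits$A$cv_auc, 0.99)
  # elastic-net grouping: a duplicated informative gene splits the weight,
  # the coefficient sum matching the single-gene fit
  counts2 <- cbind(counts, g7dup = counts[, 7])
  sig2 <- signature_coefficients(dc_counts(counts2), lab,
                                 total_count_min = 0, n_folds = 5, seed = 1)
  co2 <- sig2$fits$A$coefficients
  expect_equal(unname(co2["g7"] + co2["g7dup"]), unname(co["g7"]),
               tolerance = 0.15)
})

test_that("bulk similarity correlates coefficients with matched bulk profiles", {
  sim <- make_sc_counts(n_cells = 200, n_genes = 150, n_subsets = 2,
                        n_markers = 4, marker_effect = 2.5,
                        lib_median = 1000, dropout = 0.3, seed = 43)
  sig <- signature_coefficients(sim$counts, sim$truth$labels,
                                total_count_min = 30, n_folds = 5, seed = 1)
  # bulk sample built as a positive affine map of a cluster's coefficients
  co <- sig$fits$subset_1$coefficients
  bulk <- rbind(affine = 3 * co + 5,
                ortho = with_seed_test(44, rnorm(length(co))))
  colnames(bulk) <- sig$genes
  bs <- bulk_similarity(sig, bulk)
  expect_equal(dim(bs), c(2, 2))
  expect_equal(bs["subset_1", "affine"], 1, tolerance = 1e-12)
  expect_lt(abs(bs["subset_1", "ortho"]), 0.25)
  expect_error(bulk_similarity(sig, bulk[, 1:2]), "fewer than 3")
})

test_that("core signatures apply strict thresholds and intersect tissues", {
  t1 <- data.frame(gene = paste0("g", 1:6),
                   log2FC = c(2, 1.5, -2, 0.2, 3, -1.8),
                   FDR = c(0.001, 0.001, 0.001, 0.001, 0.5, 0.001),
                   mean_count = c(100, 100, 100, 100, 100, 10))
  t2 <- t1
  t2$log2FC[3] <- 0            # g3 no longer passes in tissue 2
  cs <- core_signature(list(spleen = t1, mln = t2))
  # |log2FC| = 1.5 exactly is excluded; FDR and mean-count arms enforced
  expect_equal(cs$per_table$spleen$up, "g1")
  expect_equal(cs$per_table$spleen$down, c("g3", "g6")[1])
  expect_equal(cs$overlap_up, "g1")
  expect_equal(cs$overlap_down, character(0))
  # identical tables: overlap equals each set
  cs2 <- core_signature(list(a = t1, b = t1))
  expect_equal(cs2$overlap_up, cs2$per_table$a$up)
  expect_error(core_signature(list(a = t1[, 1:2])), "missing required")
})

test_that("ANOVA TF selection has power at planted shifts and correct nulls", {
  set.seed(45)
  n_per <- 50
  lab <- rep(c("c1", "c2", "c3"), each = n_per)
  flat <- rnorm(150)
  shifted <- rnorm(150) + rep(c(0, 3, 6), each = n_per)   # 3 sigma steps
  v <- cbind(tf_flat = flat, tf_shift = shifted,
             tf_const = rep(1, 150))
  res <- select_variable_tfs(v, lab, tf_genes = colnames(v),
                             fdr_max = 1e-5)
  tab <- res$species_a
  expect_true(tab$selected[tab$gene == "tf_shift"])
  expect_false(tab$selected[tab$gene == "tf_flat"])
  expect_equal(tab$F[tab$gene == "tf_const"], 0)
  expect_false(tab$selected[tab$gene == "tf_const"])
  # classical F agrees with anova(lm()) as an independent route
  f_lm <- anova(lm(shifted ~ factor(lab)))$`F value`[1]
  expect_equal(tab$F[tab$gene == "tf_shift"], f_lm, tolerance = 1e-10)
  # two-species intersection through an ortholog map; disagreement is empty
  v_b <- v
  colnames(v_b) <- paste0(colnames(v), "_h")
  map <- data.frame(gene_a = colnames(v), gene_b = colnames(v_b))
  both <- suppressMessages(
    select_variable_tfs(v, lab, colnames(v), expr_b = v_b,
                        labels_b = sample(lab), ortholog_map = map,
                        fdr_max = 1e-5))
  expect_true(all(both$selected %in% colnames(v)))
  expect_false("tf_flat" %in% both$selected)
})

test_that("BH adjustment matches the sort-based oracle exactly", {
  set.seed(46)
  for (r in 1:5) {
    p <- runif(sample(5:100, 1))^2
    expect_equal(dc2scape:::bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("TF program overlap recovers planted cross-species blocks", {
  set.seed(47)
  n_tf <- 40
  # two programs with opposite SHAPES across features (per-TF z-scoring
  # removes offsets, so blocks must differ in profile shape)
  shape1 <- rep(c(3, -3), each = 4)
  base <- rbind(matrix(shape1, 20, 8, byrow = TRUE),
                matrix(-shape1, 20, 8, byrow = TRUE))
  prof_a <- base + matrix(rnorm(n_tf * 8, sd = 0.3), n_tf, 8)
  prof_b <- base + matrix(rnorm(n_tf * 8, sd = 0.3), n_tf, 8)
  rownames(prof_a) <- paste0("m", 1:n_tf)
  rownames(prof_b) <- paste0("h", 1:n_tf)
  map <- data.frame(gene_a = rownames(prof_a), gene_b = rownames(prof_b))
  res <- suppressMessages(
    tf_program_overlap(prof_a, prof_b, selected_tfs = rownames(prof_a),
                       ortholog_map = map, k = 8, seed = 1))
  # conservation: counts sum to the shared TFs
  expect_equal(sum(res$overlap), n_tf)
  # block recovery: >= 90% of TFs sit in matched cluster pairs
  expect_gte(max(apply(res$overlap, 1, max)) + 0, 1)
  matched <- sum(apply(res$overlap, 1, max))
  expect_gte(matched / n_tf, 0.9)
  # identical profiles give a permutation (diagonal-up-to-relabel) overlap
  res2 <- suppressMessages(
    tf_program_overlap(prof_a, prof_a, selected_tfs = rownames(prof_a),
                       k = 8, seed = 1))
  expect_equal(sum(apply(res2$overlap, 1, max)), n_tf)
  expect_error(suppressMessages(
    tf_program_overlap(prof_a[1:5, ], prof_b[1:5, ],
                       selected_tfs = rownames(prof_a)[1:5], k = 8)),
    "smaller k")
})

test_that("KS shift test matches theory, edge cases and exact enumeration", {
  bg <- setNames(rnorm(500), paste0("g", 1:500))
  # signature = entire background: D = 0
  all_test <- signature_shift_test(bg, names(bg))
  expect_equal(all_test$D, 0, tolerance = 1e-12)
  # signature entirely above the background maximum: D -> 1 boundary
  bg2 <- c(bg, setNames(rnorm(20, mean = 100), paste0("s", 1:20)))
  hi <- signature_shift_test(bg2, paste0("s", 1:20))
  expect_gt(hi$D, 0.95)
  # analytic location-shift limit, averaged over seeds
  ds <- vapply(1:10, function(s) {
    vals <- with_seed_test(100 + s, {
      b <- rnorm(1000)
      b[1:50] <- b[1:50] + 1
      b
    })
    names(vals) <- paste0("g", 1:1000)
    signature_shift_test(vals, paste0("g", 1:50))$D
  }, numeric(1))
  expect_lt(abs(mean(ds) - (pnorm(0.5) - pnorm(-0.5))), 0.1)
  # exact small-sample p agrees with assignment enumeration
  set.seed(48)
  for (r in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 0.8)
    kt <- suppressWarnings(stats::ks.test(x, y, exact = TRUE))
    expect_equal(kt$p.value, ks_exact_p_oracle(x, y), tolerance = 1e-9)
  }
  expect_error(signature_shift_test(bg, c("zz1", "zz2")), "fewer than 3")
})
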