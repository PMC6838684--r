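toy_gene_model_simple <- function() {
  gene_model(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                       strand = c("+", "-"), start = c(10000, 100000),
                       end = c(20000, 110000)),
    tss = data.frame(gene_id = c("gA", "gB"), pos = c(10000, 110000)),
    exons = data.frame(gene_id = c("gA", "gB"), start = c(15000, 100000),
                       end = c(15500, 100500)))
}

test_that("atlas construction filters peaks and centers fixed-width windows", {
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chrM", "chr2", "chr1"),
    start = c(1000, 2000, 3000, 4000, 5000),
    end = c(1400, 2076, 3400, 4400, 5400),     # peak 2 is width 76
    summit = c(1200, 2030, 3200, 4200, 5600))  # peak 5 summit outside
  a <- build_atlas(peaks, window = 150,
                   chromosomes = c(paste0("chr", 1:19), "chrX", "chrY"))
  rep <- attr(a, "report")
  expect_equal(rep$removed_small, 1)       # width 76 removed ("or lower")
  expect_equal(rep$removed_chrom, 1)       # chrM
  expect_equal(rep$rejected_summit, 1)
  expect_equal(nrow(a), 2)
  # window [summit - 75, summit + 75) for width 150
  expect_equal(a$wstart, a$summit - 75)
  expect_equal(a$wend, a$summit + 75)
  expect_equal(a$wend - a$wstart, rep(150, 2))
  # clipping at chromosome bounds is flagged
  p2 <- data.frame(chrom = "chr1", start = 0, end = 400, summit = 30)
  a2 <- build_atlas(p2, chrom_sizes = c(chr1 = 1e6))
  expect_true(a2$clipped[1])
  expect_equal(a2$wstart[1], 0)
})

test_that("peak annotation follows the strict class precedence", {
  gm <- toy_gene_model_simple()
  mk <- function(summit) data.frame(chrom = "chr1", start = summit - 200,
                                    end = summit + 200, summit = summit)
  atlas <- build_atlas(do.call(rbind, lapply(
    c(9500,    # 500 bp upstream of gA TSS -> promoter
      15200,   # overlaps gA exon, 5.2 kb from TSS -> exonic
      18000,   # inside gA body, no exon, 8 kb from TSS -> intronic
      25000,   # 5 kb from gA span -> intergenic
      500000), # far from everything -> unclassified
    mk)))
  ann <- annotate_peaks(atlas, gm)
  expect_equal(as.character(ann$class),
               c("promoter", "exonic", "intronic", "intergenic",
                 "unclassified"))
  expect_equal(ann$gene[1:4], rep("gA", 4))
  expect_true(is.na(ann$gene[5]))
  expect_equal(ann$distance[4], 25000 - 75 - 20000)
  # every peak gets exactly one class
  expect_false(any(is.na(ann$class)))
})

test_that("annotation matches a brute-force rule re-application on the toy atlas", {
  toy <- make_atac_toy(n_peaks = 120, n_motifs = 5, n_active_motifs = 2,
                       seed = 6)
  ann <- annotate_peaks(toy$atlas, toy$genes)
  expect_equal(as.character(ann$class),
               annotate_oracle(toy$atlas, toy$genes))
  expect_true(all(table(ann$peak_id) == 1))
  # the toy covers every annotation class
  expect_setequal(unique(as.character(ann$class)),
                  c("promoter", "exonic", "intronic", "intergenic",
                    "unclassified"))
})

test_that("median-of-ratios size factors behave under scaling", {
  expect_equal(size_factors(matrix(c(10, 20, 30, 10, 20, 30), 3, 2)),
               c(1, 1))
  sf <- size_factors(matrix(c(10, 20, 30, 20, 40, 60), 3, 2))
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(prod(sf), 1, tolerance = 1e-12)   # geometric centering
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "no peak")
})

test_that("differential accessibility applies the compound call rule", {
  set.seed(51)
  n <- 200
  base <- rlnorm(n, log(500), 0.3)
  fc <- rep(1, n); fc[1:20] <- 4                 # planted 4-fold peaks
  counts <- cbind(matrix(rpois(n * 3, base * fc), n, 3),
                  matrix(rpois(n * 3, base), n, 3))
  rownames(counts) <- paste0("p", 1:n)
  groups <- rep(c("hi", "lo"), each = 3)
  reprod <- matrix(TRUE, n, 2, dimnames = list(rownames(counts),
                                               c("hi", "lo")))
  reprod["p1", "hi"] <- FALSE                    # kills the call for p1
  expect_message(
    da <- differential_accessibility(counts, factor(groups,
                                                    c("hi", "lo")), reprod),
    "stand-in")
  expect_s3_class(da, "dc_datable")
  # planted peaks mostly called; reproducibility veto respected
  called <- da$peak_id[da$significant]
  expect_false("p1" %in% called)
  expect_gte(mean(paste0("p", 2:20) %in% called), 0.9)
  expect_lte(mean(da$significant[da$peak_id %in% paste0("p", 21:n)]), 0.05)
  # FDR monotone in p
  expect_true(all(diff(da$FDR[order(da$p)]) >= -1e-12))
  # rule arms: strong FDR but small fold change is not significant
  ext <- data.frame(peak_id = c("a", "b", "c"),
                    log2FC = c(0.4, 0.6, 0.6),
                    p = c(1e-6, 1e-6, 0.5))
  rep2 <- matrix(TRUE, 3, 2, dimnames = list(c("a", "b", "c"),
                                             c("x", "y")))
  da2 <- differential_accessibility(external_table = ext,
                                    reproducible = rep2)
  expect_equal(da2$significant, c(FALSE, TRUE, FALSE))
  expect_error(differential_accessibility(counts, groups, NULL),
               "reproducibility")
})

test_that("motif models validate and score with exact null p-values", {
  expect_error(motif_model("m", matrix(0.3, 2, 4)), "sum to 1")
  # background-equal PWM scores 0 everywhere and yields no hits
  flat <- motif_model("flat", matrix(0.25, 4, 4))
  h <- scan_motifs(c("ACGTACGT", "TTTTTTTT"), list(flat), p_threshold = 0.5)
  expect_equal(unname(h$scores[, 1]), c(0, 0))
  expect_equal(unname(h$prevalence), 0)
  # length-1 motif, P(A) = 1: score ~ log2(4) = 2 at A positions, and the
  # exact p-value of reaching that score is 0.25
  mA <- motif_model("mA", matrix(c(1, 0, 0, 0), 1, 4), prob_floor = 1e-6)
  expect_equal(dc2scape:::motif_score_pvalue(mA, round(2 / 1e-3)), 0.25)
  h2 <- scan_motifs(c("CCAC", "CCCC", "GGGG"), list(mA), p_threshold = 0.26)
  expect_equal(unname(h2$scores[1, 1]), 2, tolerance = 0.01)
  expect_equal(unname(h2$scores[2, 1]), 0)  # no A on either strand
  expect_equal(unname(h2$scores[3, 1]), 0)
  # T-rich window hits through the reverse strand
  h3 <- scan_motifs(c("TTTT"), list(mA), p_threshold = 0.26)
  expect_gt(unname(h3$scores[1, 1]), 1.9)
})

test_that("exact p-values match brute-force enumeration up to L = 6", {
  set.seed(52)
  for (L in c(2, 4, 6)) {
    m <- motif_model(paste0("m", L), dc2scape:::random_ppm(L, 0.7),
                     background = c(0.3, 0.2, 0.2, 0.3))
    d <- dc2scape:::motif_score_threshold(m, p_threshold = 0)
    tail_p <- rev(cumsum(rev(d$probs)))
    # check a spread of achievable scores, including the extremes
    idx <- unique(round(seq(1, length(tail_p), length.out = 7)))
    for (i in idx) {
      s <- d$support_lo + i - 1
      expect_equal(dc2scape:::motif_score_pvalue(m, s),
                   motif_pvalue_oracle(m, s), tolerance = 1e-9)
    }
  }
})

test_that("windows with ambiguous bases skip affected offsets", {
  mA <- motif_model("mA", matrix(c(1, 0, 0, 0), 1, 4), prob_floor = 1e-6)
  h <- scan_motifs(c("NNAN"), list(mA), p_threshold = 0.26)
  expect_equal(unname(h$scores[1, 1]), 2, tolerance = 0.01)  # lone A hits
  h2 <- scan_motifs(c("NNNN"), list(mA), p_threshold = 0.26)
  expect_equal(unname(h2$scores[1, 1]), 0)
  # motif longer than window warns and zeroes the column
  long <- motif_model("long", dc2scape:::random_ppm(10))
  expect_warning(h3 <- scan_motifs(c("ACGT"), list(long), p_threshold = 0.5),
                 "longer than window")
  expect_equal(unname(h3$scores[, 1]), 0)
})

test_that("motif prevalence filtering uses inclusive bounds and TF maps", {
  scores <- cbind(m_low = c(rep(1, 1), rep(0, 199)),     # 0.5 %
                  m_edge = c(rep(1, 2), rep(0, 198)),    # 1 % exactly
                  m_mid = c(rep(1, 40), rep(0, 160)),    # 20 %
                  m_hi = c(rep(1, 100), rep(0, 100)))    # 50 %
  hits <- structure(list(scores = scores, prevalence = colMeans(scores != 0),
                         p_threshold = 5e-4, bin = 1e-3),
                    class = "dc_motifhits")
  f <- filter_motifs(hits)
  expect_setequal(colnames(f$scores), c("m_edge", "m_mid"))
  # expressed-TF restriction
  map <- data.frame(motif = colnames(scores),
                    tf = c("t1", "t2", "t3", "t4"))
  f2 <- filter_motifs(hits, expressed_tfs = c("t2"), motif_tf_map = map)
  expect_equal(colnames(f2$scores), "m_edge")
  # per-TF best-motif reduction with an external enrichment ranking
  map$tf <- c("t1", "t1", "t1", "t2")
  enr <- data.frame(motif = colnames(scores), p = c(1e-5, 1e-4, 1e-6, 0.5))
  f3 <- filter_motifs(hits, enrichment = enr, motif_tf_map = map)
  expect_equal(colnames(f3$scores), "m_mid")   # t1's best passing motif
  expect_error(filter_motifs(hits, min_prevalence = 0.9), "all motifs")
})

test_that("lasso association recovers a noiseless single-motif effect", {
  set.seed(53)
  n <- 500
  scores <- matrix(rexp(n * 8), n, 8,
                   dimnames = list(paste0("p", 1:n), paste0("m", 1:8)))
  hits <- structure(list(scores = scores, prevalence = colMeans(scores != 0),
                         p_threshold = 5e-4, bin = 1e-3),
                    class = "dc_motifhits")
  da <- data.frame(peak_id = paste0("p", 1:n),
                   log2FC = 2 * scores[, "m3"],
                   p = 0.5, mean_count = rexp(n, 1 / 100))
  class(da) <- c("dc_datable", "data.frame")
  fit <- lasso_association(da, hits, top_n_peaks = n, n_folds = 5, seed = 1)
  expect_equal(names(which.max(abs(fit$coefficients))), "m3")
  expect_gt(fit$mean_rho, 0.99)
  # de-standardized coefficient recovers the generative slope
  expect_equal(unname(fit$coefficients_destandardized["m3"]), 2,
               tolerance = 0.05)
  # constant response errors
  da0 <- da; da0$log2FC <- 0
  expect_error(lasso_association(da0, hits, n, 5, 1), "constant response")
  # support size is non-increasing along the penalty path
  Xs <- scale(scores)
  y <- da$log2FC + rnorm(n, sd = 2)
  gfit <- glmnet::glmnet(Xs, y, alpha = 1, nlambda = 50)
  expect_true(all(diff(gfit$df) >= 0))
})

test_that("top_motifs ranks by |coefficient| with stable tie-breaking", {
  fit <- structure(list(coefficients = c(b = -2, a = 2, c = 0.5, d = 0)),
                   class = "dc_lassofit")
  tm <- top_motifs(fit, 3)
  expect_equal(tm$motif, c("a", "b", "c"))     # tie |2| broken by id
  tm2 <- top_motifs(fit, 10)
  expect_equal(nrow(tm2), 3)                   # zeros never padded in
  expect_match(attr(tm2, "note"), "3 motifs")
})

test_that("gene peak-set tests match exact Mann-Whitney enumeration", {
  set.seed(54)
  # U statistic and exact p agree with the counting-recurrence oracle
  for (r in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(5:15, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(wt$statistic), auc_pairs_oracle(x, y) * n1 * n2)
    expect_equal(wt$p.value, mw_exact_p(unname(wt$statistic), n1, n2),
                 tolerance = 1e-9)
  }
  # a gene whose peaks exceed every other fold change gets the minimal p
  da <- data.frame(peak_id = paste0("p", 1:40),
                   log2FC = c(10, 11, 12, rnorm(37)))
  map <- data.frame(peak_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene = c("gTop", "gTop", "gTop", "gNull", "gNull"))
  res <- gene_peakset_test(da, map)
  expect_equal(res$table$n_peaks[res$table$gene == "gTop"], 3)
  # the gene's own peaks are part of the all-peak background, so the U
  # statistic matches the all-pairs oracle on the inclusive comparison
  expect_equal(res$table$U[res$table$gene == "gTop"],
               auc_pairs_oracle(c(10, 11, 12), da$log2FC) * 3 * 40)
  # single tested gene: q equals p
  res1 <- gene_peakset_test(da, map[map$gene == "gTop", ])
  expect_equal(res1$table$q, res1$table$p)
  # diamond export carries sorted per-peak fold changes
  expect_equal(res$diamonds$gTop$peak_log2FC, c(10, 11, 12))
  # genes without peaks are excluded and reported
  map2 <- rbind(map, data.frame(peak_id = "absent", gene = "gGhost"))
  expect_message(res2 <- gene_peakset_test(da, map2), "without peaks")
  expect_equal(res2$excluded, "gGhost")
})

test_that("null gene peak-sets give uniform p-values", {
  set.seed(55)
  da <- data.frame(peak_id = paste0("p", 1:2000), log2FC = rnorm(2000))
  genes <- paste0("g", 1:200)
  map <- data.frame(peak_id = sample(da$peak_id, 2000, replace = FALSE),
                    gene = rep(genes, each = 10))
  res <- gene_peakset_test(da, map)
  ks <- suppressWarnings(stats::ks.test(res$table$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
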