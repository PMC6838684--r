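#' Construct a gene model
#'
#' Tabular gene annotation used for peak annotation: one row per gene plus
#' per-transcript TSS positions and exon intervals. All coordinates are
#' 0-based half-open (BED convention).
#'
#' @param genes `data.frame(gene_id, chrom, strand, start, end)`.
#' @param tss `data.frame(gene_id, pos)`; one row per transcript start.
#' @param exons `data.frame(gene_id, start, end)`.
#' @return object of class `dc_genemodel`.
#' @export
gene_model <- function(genes, tss, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "pos") %in% names(tss)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  if (any(exons$start < span$start | exons$end > span$end))
    stop("exons must lie within their gene span")
  g <- genes[match(tss$gene_id, genes$gene_id), ]
  if (any(is.na(g$gene_id))) stop("tss refers to unknown gene id")
  structure(list(genes = genes, tss = tss, exons = exons),
            class = "dc_genemodel")
}

#' Build a summit-window peak atlas
#'
#' Applies the atlas filters — peaks of size at or below `min_peak_size`
#' removed, peaks outside the allowed chromosome list removed, records whose
#' summit falls outside the peak rejected with a report — and places one
#' fixed-width window centered on every retained summit:
#' `[summit - window/2, summit + window/2)` for even widths. Windows
#' protruding past chromosome bounds are clipped and flagged when
#' chromosome sizes are supplied.
#'
#' @param peaks `data.frame(chrom, start, end, summit)` with optional
#'   `peak_id` (0-based half-open peak intervals, `summit` a position inside
#'   the peak).
#' @param window window width in bp (default 150).
#' @param min_peak_size peaks of this size or smaller are removed
#'   (default 76).
#' @param chromosomes allowed chromosome names (default chr1-chr19, chrX,
#'   chrY).
#' @param chrom_sizes optional named integer vector for clipping.
#' @return `data.frame` of class `dc_atlas` with columns `chrom`, `start`,
#'   `end`, `summit`, `peak_id`, `wstart`, `wend`, `clipped`; rejected and
#'   filtered record counts in `attr(, "report")`.
#' @export
build_atlas <- function(peaks, window = 150, min_peak_size = 76,
                        chromosomes = c(paste0("chr", 1:19), "chrX", "chrY"),
                        chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "summit") %in% names(peaks)))
  if (is.null(peaks$peak_id))
    peaks$peak_id <- paste0("peak_", seq_len(nrow(peaks)))
  n0 <- nrow(peaks)
  bad_summit <- peaks$summit < peaks$start | peaks$summit >= peaks$end
  peaks <- peaks[!bad_summit, , drop = FALSE]
  small <- (peaks$end - peaks$start) <= min_peak_size
  peaks <- peaks[!small, , drop = FALSE]
  offlist <- !(peaks$chrom %in% chromosomes)
  peaks <- peaks[!offlist, , drop = FALSE]
  half <- floor(window / 2)
  wstart <- peaks$summit - half
  wend <- wstart + window
  clipped <- rep(FALSE, nrow(peaks))
  lo <- wstart < 0
  wstart[lo] <- 0; clipped <- clipped | lo
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[peaks$chrom]
    hi <- wend > lim
    wend[hi] <- lim[hi]
    clipped <- clipped | hi
  }
  out <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                    summit = peaks$summit, peak_id = peaks$peak_id,
                    wstart = wstart, wend = wend, clipped = clipped,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "report") <- list(n_in = n0, rejected_summit = sum(bad_summit),
                              removed_small = sum(small),
                              removed_chrom = sum(offlist),
                              n_out = nrow(out), window = window)
  class(out) <- c("dc_atlas", "data.frame")
  out
}

# Gap between two half-open intervals [a1,a2) and [b1,b2); 0 when overlapping.
interval_gap <- function(a1, a2, b1, b2) pmax(0, pmax(b1 - a2, a1 - b2))

#' Annotate atlas windows with nearest genes and a positional class
#'
#' Each peak (summit window) is associated with the closest gene by genomic
#' distance (peak-edge to gene-span edge, 0 when overlapping) provided this
#' distance is at most `max_gene_distance`; ties go to the
#' lexicographically first gene id. Classification follows the strict
#' precedence: promoter (summit within `promoter_radius` of any TSS), then
#' exonic (window overlaps any exon), then intronic (window overlaps a gene
#' body), then intergenic (within `max_gene_distance` of a gene), else
#' unclassified. Every peak receives exactly one class.
#'
#' @param atlas a [build_atlas()] result.
#' @param genes a [gene_model()].
#' @param promoter_radius TSS distance for promoter calls (default 2000).
#' @param max_gene_distance association limit in bp (default 50000).
#' @return `data.frame(peak_id, gene, distance, class)`.
#' @export
annotate_peaks <- function(atlas, genes, promoter_radius = 2000,
                           max_gene_distance = 50000) {
  stopifnot(inherits(genes, "dc_genemodel"))
  if (nrow(genes$genes) == 0) stop("gene model is empty")
  gm <- genes$genes
  tss <- genes$tss
  tss$chrom <- gm$chrom[match(tss$gene_id, gm$gene_id)]
  ex <- genes$exons
  ex$chrom <- gm$chrom[match(ex$gene_id, gm$gene_id)]
  n <- nrow(atlas)
  gene_hit <- rep(NA_character_, n)
  dist_hit <- rep(NA_real_, n)
  cls <- rep("unclassified", n)
  for (i in seq_len(n)) {
    ch <- atlas$chrom[i]; ws <- atlas$wstart[i]; we <- atlas$wend[i]
    g <- gm[gm$chrom == ch, , drop = FALSE]
    if (nrow(g) > 0) {
      gaps <- interval_gap(ws, we, g$start, g$end)
      ord <- order(gaps, g$gene_id)
      if (gaps[ord[1]] <= max_gene_distance) {
        gene_hit[i] <- g$gene_id[ord[1]]
        dist_hit[i] <- gaps[ord[1]]
      }
    }
    tt <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(tt) > 0 && any(abs(atlas$summit[i] - tt$pos) <= promoter_radius)) {
      cls[i] <- "promoter"
    } else {
      ee <- ex[ex$chrom == ch, , drop = FALSE]
      if (nrow(ee) > 0 && any(ws < ee$end & ee$start < we)) {
        cls[i] <- "exonic"
      } else if (nrow(g) > 0 && any(ws < g$end & g$start < we)) {
        cls[i] <- "intronic"
      } else if (!is.na(gene_hit[i])) {
        cls[i] <- "intergenic"
      }
    }
  }
  data.frame(peak_id = atlas$peak_id, gene = gene_hit, distance = dist_hit,
             class = factor(cls, levels = c("promoter", "exonic", "intronic",
                                            "intergenic", "unclassified")),
             stringsAsFactors = FALSE)
}

#' Median-of-ratios library size factors
#'
#' Per-sample scaling factors from the median of per-peak ratios to the
#' geometric-mean reference peak, computed over peaks with all-positive
#' counts. A simple stand-in for heavier count-model normalizations.
#'
#' @param counts peaks x samples non-negative matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref_rows <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref_rows)) stop("no peak has positive counts in every sample")
  lg <- log(counts[ref_rows, , drop = FALSE])
  loggeo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - loggeo)))
}

#' Differential accessibility table with compound significance calls
#'
#' When computed internally this is a clearly labeled lightweight stand-in —
#' median-of-ratios normalization, a 0.5-pseudocount log2 fold change of
#' group means, a Welch t-test on log2-normalized counts and BH adjustment —
#' NOT a negative-binomial model; externally computed differential tables
#' (e.g. from a dedicated count model) are the recommended input via
#' `external_table`. The significance call applies the compound rule
#' exactly: `FDR < fdr_max`, `|log2FC| > lfc_min`, and the peak reproducible
#' in the condition in which it is more accessible.
#'
#' @param counts peaks x samples matrix (rownames = peak ids). Ignored when
#'   `external_table` is given.
#' @param groups length-`ncol(counts)` factor with two levels; the first
#'   level is the `log2FC > 0` direction.
#' @param reproducible peaks x 2 logical matrix (columns named by the two
#'   group levels): upstream per-condition reproducibility flags.
#' @param external_table optional `data.frame(peak_id, log2FC, p)` with
#'   optional `FDR`, `mean_count`.
#' @param fdr_max,lfc_min call thresholds (defaults 0.01 and 0.5).
#' @return `data.frame` of class `dc_datable` with columns `peak_id`,
#'   `log2FC`, `p`, `FDR`, `mean_count`, `reproducible_up`, `significant`,
#'   `direction`.
#' @export
differential_accessibility <- function(counts = NULL, groups = NULL,
                                       reproducible, external_table = NULL,
                                       fdr_max = 0.01, lfc_min = 0.5) {
  if (missing(reproducible) || is.null(reproducible))
    stop("reproducibility flags are required for significance calls")
  reproducible <- as.matrix(reproducible)
  if (is.null(external_table)) {
    counts <- as.matrix(counts)
    groups <- factor(groups)
    if (nlevels(groups) != 2) stop("exactly two groups are required")
    if (any(table(groups) < 2)) stop("need >= 2 samples per group")
    message("differential_accessibility: internal stand-in statistics ",
            "(median-of-ratios + Welch t + BH), not a negative-binomial model")
    sf <- size_factors(counts)
    norm <- sweep(counts, 2, sf, `/`)
    ia <- groups == levels(groups)[1]
    ma <- rowMeans(norm[, ia, drop = FALSE])
    mb <- rowMeans(norm[, !ia, drop = FALSE])
    lfc <- log2((ma + 0.5) / (mb + 0.5))
    lg <- log2(norm + 0.5)
    va <- apply(lg[, ia, drop = FALSE], 1, stats::var)
    vb <- apply(lg[, !ia, drop = FALSE], 1, stats::var)
    na_ <- sum(ia); nb_ <- sum(!ia)
    se2 <- va / na_ + vb / nb_
    tstat <- (rowMeans(lg[, ia, drop = FALSE]) -
                rowMeans(lg[, !ia, drop = FALSE])) / sqrt(se2)
    df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p[!is.finite(tstat)] <- 1       # zero-variance, equal-mean rows
    tab <- data.frame(peak_id = rownames(counts), log2FC = lfc, p = p,
                      mean_count = rowMeans(norm), stringsAsFactors = FALSE)
    attr_standin <- TRUE
  } else {
    tab <- external_table
    if (!all(c("peak_id", "log2FC", "p") %in% names(tab)))
      stop("external_table needs columns peak_id, log2FC, p")
    if (is.null(tab$mean_count)) tab$mean_count <- NA_real_
    attr_standin <- FALSE
  }
  rep_use <- reproducible[match(tab$peak_id, rownames(reproducible)), ,
                          drop = FALSE]
  involved <- rowSums(rep_use) > 0
  tab <- tab[involved, , drop = FALSE]
  rep_use <- rep_use[involved, , drop = FALSE]
  tab$FDR <- if (!is.null(external_table) && !is.null(external_table$FDR))
    external_table$FDR[match(tab$peak_id, external_table$peak_id)] else
      bh_adjust(tab$p)
  winning <- ifelse(tab$log2FC > 0, 1L, 2L)
  tab$reproducible_up <- rep_use[cbind(seq_len(nrow(tab)), winning)]
  tab$significant <- tab$FDR < fdr_max & abs(tab$log2FC) > lfc_min &
    tab$reproducible_up
  tab$direction <- ifelse(tab$log2FC > 0, colnames(rep_use)[1],
                          colnames(rep_use)[2])
  rownames(tab) <- NULL
  attr(tab, "stand_in") <- attr_standin
  class(tab) <- c("dc_datable", "data.frame")
  tab
}

#' Construct a motif model
#'
#' Position probability matrix over \{A, C, G, T\} with background
#' frequencies. Probabilities are floored at `prob_floor` and rows
#' renormalized so log-odds are finite.
#'
#' @param id motif identifier.
#' @param ppm L x 4 matrix, rows = positions, columns A, C, G, T, rows
#'   summing to 1 (within 1e-6) before flooring.
#' @param background length-4 base frequencies (default uniform).
#' @param prob_floor pseudo-probability floor (default 1e-3).
#' @return object of class `dc_motif`.
#' @export
motif_model <- function(id, ppm, background = rep(0.25, 4),
                        prob_floor = 1e-3) {
  ppm <- as.matrix(ppm)
  if (ncol(ppm) != 4) stop("ppm must have 4 columns (A, C, G, T)")
  if (any(abs(rowSums(ppm) - 1) > 1e-6)) stop("ppm rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  ppm <- pmax(ppm, prob_floor)
  ppm <- ppm / rowSums(ppm)
  colnames(ppm) <- c("A", "C", "G", "T")
  structure(list(id = id, ppm = ppm, background = background,
                 prob_floor = prob_floor), class = "dc_motif")
}

# Discretized log-odds weights (integer bins) for a motif; row 5 handles
# ambiguous bases with -Inf.
motif_int_weights <- function(motif, bin = 1e-3) {
  w <- log2(motif$ppm / matrix(motif$background, nrow(motif$ppm), 4,
                               byrow = TRUE))
  wi <- round(w / bin)
  rbind(t(wi), `N` = rep(-Inf, nrow(wi)))   # 5 x L: base rows, position cols
}

# Exact null distribution of the discretized total score under the
# background: dynamic programming over the integer score lattice. Returns
# the smallest integer score whose tail probability is < p_threshold.
motif_score_threshold <- function(motif, p_threshold, bin = 1e-3) {
  wi <- motif_int_weights(motif, bin)[1:4, , drop = FALSE]
  L <- ncol(wi)
  bg <- motif$background
  # iterative convolution on the running partial-sum support
  cur_lo <- 0
  p <- 1
  for (j in seq_len(L)) {
    mn <- min(wi[, j]); mx <- max(wi[, j])
    new_lo <- cur_lo + mn
    new_p <- numeric(length(p) + (mx - mn))
    for (b in 1:4) {
      off <- wi[b, j] - mn
      new_p[(1 + off):(off + length(p))] <-
        new_p[(1 + off):(off + length(p))] + bg[b] * p
    }
    p <- new_p
    cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(p)))
  hit <- which(tail_p < p_threshold)
  if (length(hit) == 0) return(list(threshold = Inf, support_lo = cur_lo,
                                    probs = p))
  list(threshold = (cur_lo + hit[1] - 1), support_lo = cur_lo, probs = p)
}

# Exact p-value of observing integer score >= s under the background.
motif_score_pvalue <- function(motif, score_int, bin = 1e-3) {
  d <- motif_score_threshold(motif, p_threshold = 0, bin = bin)
  tail_p <- rev(cumsum(rev(d$probs)))
  i <- score_int - d$support_lo + 1
  if (i <= 0) return(1)
  if (i > length(tail_p)) return(0)
  tail_p[i]
}

# Encode a DNAStringSet of equal-width windows as an integer matrix
# (A=1, C=2, G=3, T=4, other=5).
encode_windows <- function(seqs) {
  chars <- as.matrix(seqs)
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  matrix(code, nrow = length(seqs))
}

# Mirror the discretized forward weights onto the opposite strand: the score
# of the motif at a position of the reverse strand equals the score of the
# reversed, base-complemented weight matrix on the forward strand. Working on
# the integer weights keeps the two strands exactly symmetric.
reverse_complement_weights <- function(wi) {
  out <- wi[c(4, 3, 2, 1, 5), rev(seq_len(ncol(wi))), drop = FALSE]
  rownames(out) <- rownames(wi)
  out
}

# Best discretized score of one motif across all offsets of every window
# (single strand). code: windows x width integer matrix; wi: 5 x L weights.
scan_one_strand <- function(code, wi) {
  scan_best_scores(t(code), wi)
}

# Plain-R reference scanner, kept as the independent cross-check of the
# compiled routine.
scan_one_strand_r <- function(code, wi) {
  L <- ncol(wi)
  width <- ncol(code)
  n <- nrow(code)
  if (L > width) return(rep(-Inf, n))
  n_off <- width - L + 1
  S <- matrix(0, n, n_off)
  for (j in seq_len(L))
    S <- S + matrix(wi[code[, j:(j + n_off - 1), drop = FALSE], j], n)
  best <- S[, 1]
  for (o in seq_len(n_off)[-1]) best <- pmax(best, S[, o])
  best
}

#' Scan motifs over atlas windows with exact p-value thresholds
#'
#' For every window and motif, both strands are scanned at every offset with
#' discretized log-odds scores `log2(p_motif / p_background)`. The
#' per-position p-value is taken from the exact null score distribution
#' computed by dynamic programming over the discretized score lattice under
#' the background; the feature value is the maximum log-odds among positions
#' whose p-value is below `p_threshold`, and 0 when no position is
#' significant. Window positions containing ambiguous bases are skipped.
#'
#' @param windows `Biostrings::DNAStringSet` of equal-width window
#'   sequences (see [extract_windows()]), or a character vector.
#' @param motifs list of [motif_model()] objects.
#' @param p_threshold per-position significance threshold (default 5e-4).
#' @param background `"uniform"` (default) or `"sequence"` (0-order
#'   frequencies estimated from the scanned windows, overriding each
#'   motif's stored background).
#' @param bin score discretization width (default 1e-3).
#' @return object of class `dc_motifhits`: `scores` (peaks x motifs matrix,
#'   0 where no significant hit), `prevalence`, `p_threshold`.
#' @export
scan_motifs <- function(windows, motifs, p_threshold = 5e-4,
                        background = c("uniform", "sequence"), bin = 1e-3) {
  background <- match.arg(background)
  if (is.character(windows)) windows <- Biostrings::DNAStringSet(windows)
  code <- encode_windows(windows)
  if (background == "sequence") {
    tab <- tabulate(code[code <= 4], nbins = 4)
    bgf <- tab / sum(tab)
  }
  out <- matrix(0, nrow(code), length(motifs))
  colnames(out) <- vapply(motifs, `[[`, character(1), "id")
  rownames(out) <- names(windows)
  for (m in seq_along(motifs)) {
    mot <- motifs[[m]]
    if (background == "sequence")
      mot <- motif_model(mot$id, mot$ppm, background = bgf,
                         prob_floor = mot$prob_floor)
    if (nrow(mot$ppm) > ncol(code)) {
      warning("motif '", mot$id, "' longer than window; zero column")
      next
    }
    thr <- motif_score_threshold(mot, p_threshold, bin = bin)$threshold
    wi <- motif_int_weights(mot, bin)
    best <- pmax(scan_one_strand(code, wi),
                 scan_one_strand(code, reverse_complement_weights(wi)))
    sig <- is.finite(best) & best >= thr
    out[sig, m] <- best[sig] * bin
  }
  structure(list(scores = out,
                 prevalence = colMeans(out != 0),
                 p_threshold = p_threshold, bin = bin),
            class = "dc_motifhits")
}

#' Filter motif features by prevalence, TF expression and per-TF reduction
#'
#' Motif columns with prevalence outside `[min_prevalence, max_prevalence]`
#' (inclusive boundaries) are removed; motifs without an expressed
#' transcription factor are removed when an expression list and motif-TF map
#' are given; and when a per-motif enrichment ranking is supplied, only each
#' TF's best-ranked motif with `p < max_enrichment_p` is kept.
#'
#' @param hits a [scan_motifs()] result.
#' @param min_prevalence,max_prevalence inclusive prevalence bounds
#'   (defaults 0.01 and 0.40).
#' @param expressed_tfs optional character vector of expressed TF gene ids.
#' @param motif_tf_map optional `data.frame(motif, tf)`.
#' @param enrichment optional `data.frame(motif, p)` — an externally
#'   computed enrichment ranking (e.g. from a dedicated enrichment tool)
#'   driving the per-TF best-motif reduction.
#' @param max_enrichment_p enrichment cutoff for the reduction (default
#'   0.001).
#' @return a filtered `dc_motifhits`.
#' @export
filter_motifs <- function(hits, min_prevalence = 0.01, max_prevalence = 0.40,
                          expressed_tfs = NULL, motif_tf_map = NULL,
                          enrichment = NULL, max_enrichment_p = 0.001) {
  stopifnot(inherits(hits, "dc_motifhits"))
  keep <- hits$prevalence >= min_prevalence & hits$prevalence <= max_prevalence
  ids <- colnames(hits$scores)
  if (!is.null(expressed_tfs)) {
    if (is.null(motif_tf_map)) stop("motif_tf_map required with expressed_tfs")
    tf_of <- motif_tf_map$tf[match(ids, motif_tf_map$motif)]
    keep <- keep & !is.na(tf_of) & tf_of %in% expressed_tfs
  }
  if (!is.null(enrichment)) {
    if (is.null(motif_tf_map)) stop("motif_tf_map required for per-TF reduction")
    p <- enrichment$p[match(ids, enrichment$motif)]
    tf_of <- motif_tf_map$tf[match(ids, motif_tf_map$motif)]
    ok <- keep & !is.na(p) & p < max_enrichment_p & !is.na(tf_of)
    best <- tapply(seq_along(ids)[ok], tf_of[ok], function(ii)
      ii[order(p[ii], ids[ii])][1])
    keep <- seq_along(ids) %in% unlist(best)
  }
  if (!any(keep)) stop("all motifs removed by filtering")
  structure(list(scores = hits$scores[, keep, drop = FALSE],
                 prevalence = hits$prevalence[keep],
                 p_threshold = hits$p_threshold, bin = hits$bin),
            class = "dc_motifhits")
}

#' Lasso association of motif scores with differential accessibility
#'
#' Fits `y ~ X w` where `y` is the per-peak accessibility log2 fold change
#' and `X` the motif score features, restricted to the `top_n_peaks` peaks
#' with the highest normalized mean counts. Features are standardized to
#' zero mean and unit variance; an L1-penalized least-squares path (100
#' log-spaced penalties) is fitted and the penalty minimizing held-out
#' squared error under `n_folds`-fold cross-validation is selected.
#' Reported performance is the mean across folds of the Spearman rho
#' between held-out predictions and observed fold changes.
#'
#' @param da a [differential_accessibility()] table.
#' @param hits a [scan_motifs()]/[filter_motifs()] feature matrix.
#' @param top_n_peaks peaks used, ranked by `mean_count` (default 20000; all
#'   peaks when fewer are available).
#' @param n_folds cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @return object of class `dc_lassofit`: `coefficients` (standardized
#'   scale), `coefficients_destandardized`, `lambda`, `fold_rho`,
#'   `mean_rho`, `n_peaks`.
#' @export
lasso_association <- function(da, hits, top_n_peaks = 20000, n_folds = 5,
                              seed = 1) {
  stopifnot(inherits(hits, "dc_motifhits"))
  X_all <- hits$scores
  common <- intersect(da$peak_id, rownames(X_all))
  da <- da[match(common, da$peak_id), , drop = FALSE]
  X_all <- X_all[common, , drop = FALSE]
  ord <- order(-da$mean_count, da$peak_id)
  sel <- ord[seq_len(min(top_n_peaks, length(ord)))]
  y <- da$log2FC[sel]
  if (stats::sd(y) == 0) stop("constant response: no differential signal to model")
  X <- X_all[sel, , drop = FALSE]
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  usable <- sdv > 0
  Xs <- sweep(X[, usable, drop = FALSE], 2, mu[usable])
  Xs <- sweep(Xs, 2, sdv[usable], `/`)
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), length(y))))
  cv <- glmnet::cv.glmnet(Xs, y, alpha = 1, nlambda = 100, foldid = foldid,
                          type.measure = "mse", standardize = FALSE)
  lam <- cv$lambda.min
  co <- stats::setNames(numeric(ncol(X_all)), colnames(X_all))
  co[colnames(Xs)] <- as.numeric(stats::coef(cv, s = lam))[-1]
  fold_rho <- vapply(seq_len(n_folds), function(f) {
    tr <- foldid != f
    if (stats::sd(y[!tr]) == 0) return(NA_real_)   # rho undefined
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], alpha = 1,
                          lambda = cv$lambda, standardize = FALSE)
    pred <- as.numeric(stats::predict(fit, Xs[!tr, , drop = FALSE], s = lam))
    if (stats::sd(pred) == 0) return(0)            # no predictive ability
    stats::cor(pred, y[!tr], method = "spearman")
  }, numeric(1))
  if (anyNA(fold_rho))
    warning("fold(s) with constant response excluded from rho")
  dest <- co
  dest[colnames(Xs)] <- co[colnames(Xs)] / sdv[usable]
  structure(list(coefficients = co, coefficients_destandardized = dest,
                 lambda = lam, fold_rho = fold_rho,
                 mean_rho = mean(fold_rho, na.rm = TRUE),
                 n_peaks = length(y)), class = "dc_lassofit")
}

#' Rank motifs by absolute lasso coefficient
#'
#' @param fit a [lasso_association()] result.
#' @param n motifs to return (default 50); when `n` exceeds the nonzero
#'   support all nonzero motifs are returned with a note attribute.
#' @return `data.frame(motif, coefficient)` sorted by |coefficient|
#'   descending, ties broken by motif id.
#' @export
top_motifs <- function(fit, n = 50) {
  stopifnot(inherits(fit, "dc_lassofit"))
  co <- fit$coefficients
  nz <- co[co != 0]
  ord <- order(-abs(nz), names(nz))
  m <- min(n, length(nz))
  out <- data.frame(motif = names(nz)[ord][seq_len(m)],
                    coefficient = unname(nz[ord][seq_len(m)]),
                    stringsAsFactors = FALSE)
  if (n > length(nz))
    attr(out, "note") <- sprintf("only %d motifs have nonzero coefficients",
                                 length(nz))
  out
}

#' Per-gene peak-set shift test (diamond-plot data)
#'
#' For each gene with associated peaks, a two-sided Mann-Whitney U test
#' compares the gene's peak accessibility log2 fold changes with those of
#' all peaks, BH-adjusted across the tested genes. Per-gene ordered peak
#' fold changes (plus an optional expression fold-change slot) are returned
#' for diamond-plot export.
#'
#' @param da a [differential_accessibility()] table.
#' @param peak_gene_map `data.frame(peak_id, gene)`.
#' @param genes genes to test (default: all genes in the map); genes with
#'   zero peaks in `da` are excluded and reported.
#' @param expression_log2fc optional named vector of gene expression fold
#'   changes for the diamond export.
#' @return list with `table` (`gene`, `U`, `p`, `q`, `mean_log2FC`,
#'   `n_peaks`), `diamonds` (per-gene sorted peak log2FCs and
#'   `expr_log2FC`), `excluded`.
#' @export
gene_peakset_test <- function(da, peak_gene_map, genes = NULL,
                              expression_log2fc = NULL) {
  if (is.null(genes)) genes <- sort(unique(peak_gene_map$gene))
  all_lfc <- da$log2FC
  rows <- list(); diamonds <- list(); excluded <- character(0)
  for (g in genes) {
    pk <- peak_gene_map$peak_id[peak_gene_map$gene == g]
    lfc <- da$log2FC[da$peak_id %in% pk]
    if (length(lfc) == 0) { excluded <- c(excluded, g); next }
    wt <- suppressWarnings(stats::wilcox.test(lfc, all_lfc,
                                              alternative = "two.sided"))
    rows[[g]] <- data.frame(gene = g, U = unname(wt$statistic),
                            p = wt$p.value, mean_log2FC = mean(lfc),
                            n_peaks = length(lfc), stringsAsFactors = FALSE)
    diamonds[[g]] <- list(peak_log2FC = sort(lfc),
                          expr_log2FC = if (!is.null(expression_log2fc))
                            unname(expression_log2fc[g]) else NA_real_)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$q <- bh_adjust(tab$p)
  tab <- tab[, c("gene", "U", "p", "q", "mean_log2FC", "n_peaks")]
  if (length(excluded) > 0)
    message(length(excluded), " gene(s) without peaks excluded")
  list(table = tab, diamonds = diamonds, excluded = excluded)
}
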