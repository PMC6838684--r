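#' Read a 10X-convention count matrix (MatrixMarket triplet + TSVs)
#'
#' @param mtx path to the `.mtx` file (genes x cells or cells x genes; set
#'   `cells_in_rows` accordingly — the 10X convention stores genes in rows).
#' @param barcodes path to the barcodes TSV (one cell id per line).
#' @param genes path to the genes TSV (first column = gene id).
#' @param cells_in_rows whether the matrix stores cells in rows
#'   (default FALSE, the 10X convention).
#' @param ... passed to [dc_counts()] (e.g. `mito_prefixes`).
#' @return a [dc_counts()] object.
#' @export
read_counts_mtx <- function(mtx, barcodes, genes, cells_in_rows = FALSE, ...) {
  m <- Matrix::readMM(mtx)
  bc <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)[, 1]
  gn <- utils::read.delim(genes, header = FALSE, stringsAsFactors = FALSE)[, 1]
  if (!cells_in_rows) m <- Matrix::t(m)
  dc_counts(m, cell_ids = bc, gene_ids = gn, ...)
}

#' Write a count matrix in the 10X MTX convention
#'
#' @param x a [dc_counts()] object.
#' @param dir output directory (created if needed); files `matrix.mtx`,
#'   `barcodes.tsv`, `genes.tsv` are written (genes in rows).
#' @return the directory, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "dc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Read a dense CSV count matrix (cells in rows)
#'
#' @param path CSV with a header of gene ids and first column of cell ids.
#' @param ... passed to [dc_counts()].
#' @return a [dc_counts()] object.
#' @export
read_counts_csv <- function(path, ...) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  dc_counts(as.matrix(df), ...)
}

#' Write an expression matrix (or any matrix) as TSV
#' @param x a [dc_expr()] or matrix.
#' @param path output path.
#' @export
write_expr_tsv <- function(x, path) {
  v <- as_expr_values(x)
  utils::write.table(v, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read/write a two-column cell partition TSV
#'
#' @param path TSV with columns `cell_id`, `label` (header optional on read).
#' @return named character vector of labels.
#' @export
read_partition <- function(path) {
  first <- utils::read.delim(path, nrows = 1, header = FALSE,
                             stringsAsFactors = FALSE)
  header <- identical(as.character(first[1, 1]), "cell_id")
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[, 2]), df[, 1])
}

#' @rdname read_partition
#' @param labels named character vector (names = cell ids).
#' @export
write_partition <- function(labels, path) {
  df <- data.frame(cell_id = names(labels), label = unname(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  out
}

#' Write a marker table as TSV with stable column names
#' @param table a [marker_table()] (or [select_markers()]) result.
#' @param path output path.
#' @export
write_marker_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peak records with summits from BED-like files
#'
#' Accepts either a MACS2 summit BED (chrom, summit_start, summit_end, name)
#' plus matching peak intervals, or a narrowPeak-style table whose 10th
#' column is the summit offset from `start`. A plain 4+ column BED with a
#' `summit` column also works.
#'
#' @param path BED/narrowPeak path (no header).
#' @return `data.frame(chrom, start, end, summit, peak_id)`.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 10) {          # narrowPeak: summit offset in column 10
    out <- data.frame(chrom = df[, 1], start = df[, 2], end = df[, 3],
                      summit = df[, 2] + df[, 10],
                      peak_id = as.character(df[, 4]),
                      stringsAsFactors = FALSE)
  } else if (ncol(df) >= 4 && all(df[, 3] - df[, 2] == 1)) {
    # summit BED: 1 bp intervals at the summit
    out <- data.frame(chrom = df[, 1], start = df[, 2], end = df[, 3],
                      summit = df[, 2], peak_id = as.character(df[, 4]),
                      stringsAsFactors = FALSE)
  } else {
    stop("unrecognized peak BED dialect: need narrowPeak or summit BED")
  }
  out
}

#' Write atlas windows as BED
#' @param atlas a [build_atlas()] result.
#' @param path output path.
#' @export
write_atlas_bed <- function(atlas, path) {
  utils::write.table(atlas[, c("chrom", "wstart", "wend", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Extract atlas window sequences from a genome
#'
#' @param genome a `Biostrings::DNAStringSet` (names = chromosomes) or a
#'   FASTA path.
#' @param atlas a [build_atlas()] result.
#' @return `DNAStringSet` of window sequences named by peak id.
#' @export
extract_windows <- function(genome, atlas) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(atlas$chrom), names(genome))
  if (length(missing) > 0)
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  out <- character(nrow(atlas))
  for (ch in unique(atlas$chrom)) {
    i <- atlas$chrom == ch
    out[i] <- substring(as.character(genome[[ch]]), atlas$wstart[i] + 1,
                        atlas$wend[i])
  }
  seqs <- Biostrings::DNAStringSet(out)
  names(seqs) <- atlas$peak_id
  seqs
}

#' Read motifs from MEME minimal format
#'
#' @param path MEME minimal-format file.
#' @param prob_floor passed to [motif_model()].
#' @return list of [motif_model()] objects.
#' @export
read_meme <- function(path, prob_floor = 1e-3) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0) {
    f <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(f[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF", lines)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[starts[i]:length(lines)])[1] +
      starts[i] - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    ppm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    out[[i]] <- motif_model(id, ppm, background = bg, prob_floor = prob_floor)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of [motif_model()] objects.
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m$ppm)), con)
    writeLines(apply(m$ppm, 1, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read/write a gene model as a flat TSV
#'
#' The flat dialect has one row per feature: columns `gene_id`, `chrom`,
#' `strand`, `feature` (`gene`/`tss`/`exon`), `start`, `end` (for `tss`,
#' `start` holds the position).
#'
#' @param path TSV path.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- df[df$feature == "gene", ]
  t <- df[df$feature == "tss", ]
  e <- df[df$feature == "exon", ]
  gene_model(genes = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                strand = g$strand, start = g$start,
                                end = g$end, stringsAsFactors = FALSE),
             tss = data.frame(gene_id = t$gene_id, pos = t$start,
                              stringsAsFactors = FALSE),
             exons = data.frame(gene_id = e$gene_id, start = e$start,
                                end = e$end, stringsAsFactors = FALSE))
}

#' @rdname read_gene_model
#' @param model a [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  g <- model$genes
  rows <- rbind(
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               feature = "gene", start = g$start, end = g$end),
    data.frame(gene_id = model$tss$gene_id,
               chrom = g$chrom[match(model$tss$gene_id, g$gene_id)],
               strand = g$strand[match(model$tss$gene_id, g$gene_id)],
               feature = "tss", start = model$tss$pos,
               end = model$tss$pos + 1L),
    data.frame(gene_id = model$exons$gene_id,
               chrom = g$chrom[match(model$exons$gene_id, g$gene_id)],
               strand = g$strand[match(model$exons$gene_id, g$gene_id)],
               feature = "exon", start = model$exons$start,
               end = model$exons$end))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
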