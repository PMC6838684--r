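#' Construct a cell-by-gene count matrix container
#'
#' Wraps a non-negative integer cells x genes matrix together with cell and
#' gene identifiers and a per-gene mitochondrial mask. All preprocessing
#' functions consume and return this container.
#'
#' @param counts cells x genes matrix (base or \code{Matrix} sparse) of
#'   non-negative integer molecule counts. Row names are taken as cell ids
#'   and column names as gene ids when `cell_ids`/`gene_ids` are missing.
#' @param cell_ids,gene_ids unique character identifiers.
#' @param mito_prefixes gene-id prefixes marking mitochondrial genes;
#'   matching is case-sensitive on each prefix in turn.
#' @param mito_mask optional explicit logical mask (overrides prefixes).
#' @return object of class `dc_counts` with elements `counts`, `cell_ids`,
#'   `gene_ids`, `mito_mask`.
#' @export
dc_counts <- function(counts, cell_ids = rownames(counts),
                      gene_ids = colnames(counts),
                      mito_prefixes = c("mt-", "MT-"), mito_mask = NULL) {
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("identifier lengths must match matrix dimensions")
  if (min(counts) < 0) stop("counts must be non-negative")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(mito_mask)) {
    mito_mask <- Reduce(`|`, lapply(mito_prefixes, function(p)
      startsWith(gene_ids, p)))
  }
  if (length(mito_mask) != length(gene_ids))
    stop("mito_mask length must equal gene count")
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 mito_mask = as.logical(mito_mask)),
            class = "dc_counts")
}

#' @export
print.dc_counts <- function(x, ...) {
  cat(sprintf("dc_counts: %d cells x %d genes (%d mitochondrial genes)\n",
              length(x$cell_ids), length(x$gene_ids), sum(x$mito_mask)))
  invisible(x)
}

#' Construct an expression matrix container
#'
#' @param values cells x genes real matrix with finite entries.
#' @param state one of `"normalized"`, `"imputed"`, `"residualized"`.
#' @param cell_ids,gene_ids identifiers (default from dimnames).
#' @return object of class `dc_expr`.
#' @export
dc_expr <- function(values, state = c("normalized", "imputed", "residualized"),
                    cell_ids = rownames(values), gene_ids = colnames(values)) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids), state = state),
            class = "dc_expr")
}

#' @export
print.dc_expr <- function(x, ...) {
  cat(sprintf("dc_expr (%s): %d cells x %d genes\n", x$state,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept either a dc_expr or a bare matrix in analysis functions.
as_expr_values <- function(expr) {
  if (inherits(expr, "dc_expr")) expr$values else as.matrix(expr)
}
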