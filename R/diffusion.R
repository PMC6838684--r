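#' Adaptive Gaussian cell-affinity graph
#'
#' For each cell i the Gaussian affinity `exp(-(d_ij/sigma_i)^alpha)` is
#' placed on its `k` nearest neighbors (Euclidean metric on the embedding),
#' where `sigma_i` is the distance to the `ka`-th nearest neighbor. The
#' matrix is symmetrized as `(A + t(A))/2` and self-affinities are set to 1.
#'
#' @param embedding cells x K numeric matrix (e.g. PCA scores).
#' @param k number of neighbors receiving affinity (default 30).
#' @param ka adaptive bandwidth index (default 10); must satisfy `ka < k`.
#' @param alpha kernel decay exponent; 2 gives the plain Gaussian, larger
#'   values give the heavier-tailed alpha-decay variant.
#' @return object of class `dc_affinity`: `weights` (sparse symmetric
#'   cells x cells), `params`.
#' @export
adaptive_affinity <- function(embedding, k = 30, ka = 10, alpha = 2) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (ka >= k) stop("ka must be smaller than k")
  d <- as.matrix(stats::dist(embedding))
  ii <- jj <- vector("list", n)
  vv <- vector("list", n)
  warned <- FALSE
  for (i in seq_len(n)) {
    di <- d[i, ]
    ord <- order(di)
    ord <- ord[ord != i]           # drop self (robust to duplicate points)
    nbrs <- ord[seq_len(k)]
    sigma <- di[ord[ka]]
    if (sigma == 0) {
      pos <- di[nbrs][di[nbrs] > 0]
      if (length(pos) == 0) pos <- 1    # all duplicates: kernel value 1 anyway
      sigma <- min(pos)
      warned <- TRUE
    }
    ii[[i]] <- rep(i, k); jj[[i]] <- nbrs
    vv[[i]] <- exp(-(di[nbrs] / sigma)^alpha)
  }
  if (warned) warning("zero adaptive bandwidth replaced by smallest positive neighbor distance")
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  Matrix::diag(A) <- 1
  rn <- rownames(embedding)
  if (!is.null(rn)) dimnames(A) <- list(rn, rn)
  structure(list(weights = A, params = list(k = k, ka = ka, alpha = alpha)),
            class = "dc_affinity")
}

#' Row-stochastic Markov normalization of an affinity graph
#'
#' @param graph a [adaptive_affinity()] result (or bare non-negative matrix).
#' @return object of class `dc_transition` with the row-stochastic sparse
#'   `matrix`.
#' @export
markov_normalize <- function(graph) {
  A <- if (inherits(graph, "dc_affinity")) graph$weights else
    Matrix::Matrix(graph, sparse = TRUE)
  rs <- Matrix::rowSums(A)
  if (any(rs == 0)) stop("isolated cell(s) with zero affinity row sum")
  M <- A / rs
  structure(list(matrix = M), class = "dc_transition")
}

#' Diffusion imputation of expression values
#'
#' Smooths expression by powering the row-stochastic transition operator:
#' `X_imputed = M^t X`, computed by `t` repeated sparse multiplications
#' (never an explicit dense matrix power). `t = 0` is the identity.
#'
#' @param expr a [dc_expr()] or matrix (cells x genes).
#' @param op a [markov_normalize()] transition operator.
#' @param t non-negative integer diffusion time (default 4).
#' @return a [dc_expr()] with `state = "imputed"`.
#' @export
impute_expression <- function(expr, op, t = 4) {
  stopifnot(inherits(op, "dc_transition"), t >= 0, t == round(t))
  v <- as_expr_values(expr)
  if (nrow(v) != nrow(op$matrix)) stop("dimension mismatch between expr and operator")
  out <- v
  for (s in seq_len(t)) out <- as.matrix(op$matrix %*% out)
  dc_expr(out, state = "imputed", cell_ids = rownames(v), gene_ids = colnames(v))
}

#' Imputation stability across kernel parameters
#'
#' Recomputes the imputation over a (k, t) grid and reports, per grid point,
#' the median across genes of the squared Pearson correlation with the
#' reference imputation. Zero-variance genes are excluded from the median.
#'
#' @param expr expression to impute.
#' @param embedding embedding on which affinities are built.
#' @param k_values,t_values grid axes.
#' @param reference `c(k, t)` pair that serves as the reference (must lie in
#'   the grid).
#' @param ka adaptive index used throughout.
#' @return object of class `dc_stability`: `grid` (length(k) x length(t)
#'   matrix of median R^2), `k_values`, `t_values`, `reference`.
#' @export
imputation_stability <- function(expr, embedding, k_values, t_values,
                                 reference = c(30, 4), ka = 10) {
  if (!(reference[1] %in% k_values) || !(reference[2] %in% t_values))
    stop("reference (k, t) must be contained in the grid")
  v <- as_expr_values(expr)
  impute_grid <- function(k) {
    op <- markov_normalize(adaptive_affinity(embedding, k = k, ka = min(ka, k - 1)))
    cur <- v
    res <- vector("list", length(t_values))
    tm <- 0
    for (tt in sort(unique(t_values))) {
      while (tm < tt) { cur <- as.matrix(op$matrix %*% cur); tm <- tm + 1 }
      res[t_values == tt] <- list(cur)
    }
    res
  }
  by_k <- lapply(k_values, impute_grid)
  ref <- by_k[[match(reference[1], k_values)]][[match(reference[2], t_values)]]
  sd_ref <- apply(ref, 2, stats::sd)
  grid <- matrix(NA_real_, length(k_values), length(t_values),
                 dimnames = list(paste0("k", k_values), paste0("t", t_values)))
  for (i in seq_along(k_values)) for (j in seq_along(t_values)) {
    x <- by_k[[i]][[j]]
    sd_x <- apply(x, 2, stats::sd)
    ok <- sd_ref > 0 & sd_x > 0
    if (sum(ok) < 2) stop("fewer than 2 genes with variance")
    r <- vapply(which(ok), function(g) stats::cor(x[, g], ref[, g]), numeric(1))
    grid[i, j] <- stats::median(r^2)
  }
  structure(list(grid = grid, k_values = k_values, t_values = t_values,
                 reference = reference), class = "dc_stability")
}

#' Multi-scale diffusion map of a cell-affinity graph
#'
#' Eigendecomposition of the symmetric conjugate `D^{-1/2} A D^{-1/2}`,
#' mapped back to right eigenvectors of the Markov operator `D^{-1} A`. The
#' trivial stationary component (eigenvalue 1) is dropped. Each retained
#' component i is additionally scaled by `lambda_i / (1 - lambda_i)` to give
#' multi-scale coordinates whose Euclidean distances approximate diffusion
#' distances. The number of informative components is selected at the
#' largest relative eigen gap `(lambda_i - lambda_{i+1}) / lambda_i` unless
#' overridden.
#'
#' @param graph a [adaptive_affinity()] result.
#' @param max_components number of non-trivial components to compute.
#' @param n_selected manual override of the eigen-gap selection.
#' @return object of class `dc_diffmap`: `eigenvalues`, `components`,
#'   `multiscale`, `n_selected`.
#' @export
diffusion_map <- function(graph, max_components = 10, n_selected = NULL) {
  A <- if (inherits(graph, "dc_affinity")) graph$weights else
    Matrix::Matrix(graph, sparse = TRUE)
  n <- nrow(A)
  if (max_components >= n) stop("max_components must be smaller than cells")
  dvec <- Matrix::rowSums(A)
  if (any(dvec == 0)) stop("isolated cell(s) in the graph")
  dinv <- 1 / sqrt(dvec)
  S <- as.matrix(A * outer(dinv, dinv))
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lambda <- eg$values
  if (length(lambda) > 1 && lambda[2] > 1 - 1e-10)
    stop("disconnected graph: eigenvalue 1 has multiplicity > 1; analyze components separately")
  idx <- 1 + seq_len(max_components)          # drop trivial lambda_0 = 1
  lam <- lambda[idx]
  psi <- eg$vectors[, idx, drop = FALSE] * dinv
  # unit-norm columns with deterministic sign (largest-magnitude entry positive)
  for (j in seq_len(ncol(psi))) {
    psi[, j] <- psi[, j] / sqrt(sum(psi[, j]^2))
    if (psi[which.max(abs(psi[, j])), j] < 0) psi[, j] <- -psi[, j]
  }
  if (is.null(n_selected)) {
    pos <- lam[lam > 0]
    gaps <- (pos[-length(pos)] - pos[-1]) / pos[-length(pos)]
    n_selected <- if (length(gaps) == 0) 1L else which.max(gaps)
  }
  multiscale <- sweep(psi, 2, lam / (1 - lam), `*`)
  rownames(psi) <- rownames(multiscale) <- rownames(A)
  colnames(psi) <- colnames(multiscale) <- paste0("DC", seq_along(lam))
  structure(list(eigenvalues = lam, components = psi, multiscale = multiscale,
                 n_selected = as.integer(n_selected)), class = "dc_diffmap")
}

#' Pairwise distance provider on multi-scale diffusion coordinates
#'
#' Euclidean distances in the selected multi-scale coordinates. The provider
#' supports full pairwise queries ([as.matrix()]) and k-NN queries
#' ([knn_query()]). A bare coordinate matrix can also be wrapped directly.
#'
#' @param dm a [diffusion_map()] result or a coordinate matrix.
#' @param n_components how many leading coordinates to use (defaults to the
#'   diffusion map's `n_selected`).
#' @return object of class `dc_dist`.
#' @export
multiscale_distances <- function(dm, n_components = NULL) {
  coords <- if (inherits(dm, "dc_diffmap")) {
    if (is.null(n_components)) n_components <- dm$n_selected
    dm$multiscale[, seq_len(n_components), drop = FALSE]
  } else as.matrix(dm)
  if (ncol(coords) < 1) stop("need at least one coordinate")
  structure(list(coords = coords), class = "dc_dist")
}

#' @export
as.matrix.dc_dist <- function(x, ...) as.matrix(stats::dist(x$coords))

#' k-nearest-neighbor query on a distance provider
#'
#' @param provider a [multiscale_distances()] object.
#' @param k neighbors per cell (self excluded). Ties at the k-th distance
#'   are broken by cell-id (row) order for determinism.
#' @return integer matrix cells x k of neighbor row indices.
#' @export
knn_query <- function(provider, k) {
  stopifnot(inherits(provider, "dc_dist"), k >= 1)
  d <- as.matrix(provider)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of cells")
  out <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k))
  if (k == 1) matrix(out, ncol = 1) else t(out)
}

n_cells_dist <- function(provider) nrow(provider$coords)
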