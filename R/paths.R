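#' k-nearest-neighbor cell graph from a distance provider
#'
#' Each cell gets directed edges to its `k` nearest others; exact ties at the
#' k-th distance are broken by cell index order, so the graph is bitwise
#' reproducible. Edge weights are the distances.
#'
#' @param distances a [multiscale_distances()] provider (or coordinate
#'   matrix, which is wrapped).
#' @param k neighbors per cell (default 15).
#' @return object of class `dc_cellgraph`: `edges` (integer matrix `from`,
#'   `to` with weight column `dist`), `n`, `k`, `dist` (the full symmetric
#'   distance matrix, kept for neighborhood queries).
#' @export
knn_graph <- function(distances, k = 15) {
  if (!inherits(distances, "dc_dist")) distances <- multiscale_distances(distances)
  if (k < 1) stop("k must be >= 1")
  d <- as.matrix(distances)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- knn_query(distances, k)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  edges <- cbind(from = from, to = to, dist = d[cbind(from, to)])
  structure(list(edges = edges, n = n, k = k, dist = d,
                 ids = rownames(d)), class = "dc_cellgraph")
}

# Adjacency list (list of data per node: to, w), optionally symmetrized.
adjacency_list <- function(edges, n, directed = FALSE) {
  if (!directed) {
    edges <- rbind(edges, edges[, c(2, 1, 3), drop = FALSE])
    key <- paste(edges[, 1], edges[, 2])
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  split.data.frame(edges[, 2:3, drop = FALSE], factor(edges[, 1], levels = seq_len(n)))
}

# Dijkstra with deterministic tie-breaking: among equal tentative distances
# the lexicographically smallest predecessor index wins.
dijkstra_path <- function(adj, n, source, target) {
  dist <- rep(Inf, n); dist[source] <- 0
  pred <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    if (u == target) break
    visited[u] <- TRUE
    e <- adj[[u]]
    if (NROW(e) > 0) {
      v <- e[, 1]; nd <- dist[u] + e[, 2]
      sel <- nd < dist[v] | (nd == dist[v] & !is.na(pred[v]) & u < pred[v])
      dist[v[sel]] <- nd[sel]
      pred[v[sel]] <- u
    }
  }
  if (!is.finite(dist[target])) return(NULL)
  path <- target
  while (path[1] != source) path <- c(pred[path[1]], path)
  path
}

#' Exact shortest path between two cells
#'
#' Dijkstra's algorithm on the cell graph. Edges are treated as undirected
#' with their symmetric distances by default (the k-NN relation itself is
#' asymmetric); set `directed = TRUE` to respect edge direction. Equal-cost
#' alternatives are resolved toward the lexicographically smallest
#' predecessor index, so results are deterministic.
#'
#' @param graph a [knn_graph()].
#' @param source,target cell indices (1-based) or cell ids.
#' @param directed respect edge direction (default FALSE).
#' @return list `path` (indices), `step_sizes` (consecutive edge distances),
#'   `total` (sum). `source == target` gives a single-node path of total 0.
#' @export
shortest_path <- function(graph, source, target, directed = FALSE) {
  stopifnot(inherits(graph, "dc_cellgraph"))
  source <- resolve_cell(graph, source)
  target <- resolve_cell(graph, target)
  if (source == target)
    return(list(path = source, step_sizes = numeric(0), total = 0))
  adj <- adjacency_list(graph$edges, graph$n, directed = directed)
  path <- dijkstra_path(adj, graph$n, source, target)
  if (is.null(path)) {
    comp <- reachable_set(adj, graph$n, source)
    stop(sprintf("target unreachable from source: source component has %d of %d cells",
                 length(comp), graph$n))
  }
  steps <- graph$dist[cbind(path[-length(path)], path[-1])]
  list(path = path, step_sizes = unname(steps), total = sum(steps))
}

resolve_cell <- function(graph, cell) {
  if (is.character(cell)) {
    i <- match(cell, graph$ids)
    if (is.na(i)) stop("unknown cell id: ", cell)
    return(i)
  }
  as.integer(cell)
}

reachable_set <- function(adj, n, source) {
  seen <- rep(FALSE, n); seen[source] <- TRUE
  stack <- source
  while (length(stack) > 0) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    e <- adj[[u]]
    if (NROW(e) > 0) {
      nxt <- e[!seen[e[, 1]], 1]
      seen[nxt] <- TRUE
      stack <- c(stack, nxt)
    }
  }
  which(seen)
}

#' Sample shortest paths from randomized k-l-NN subgraphs
#'
#' For each sample, `l` of each cell's `k` outgoing edges are retained
#' uniformly at random (without replacement, fresh per sample, one seeded
#' RNG stream for the whole ensemble) and the shortest path from source to
#' target is computed on the subgraph. Samples in which the target becomes
#' unreachable are recorded as failures and excluded downstream; the failure
#' rate is reported.
#'
#' @inheritParams shortest_path
#' @param l edges retained per cell (`l <= k`); `l = k` reproduces the
#'   full-graph shortest path in every sample.
#' @param n_samples number of sampled subgraphs (default 100).
#' @param seed RNG seed.
#' @return object of class `dc_pathensemble`: `paths` (list of index
#'   vectors), `step_sizes`, `totals`, `n_failures`, `failure_rate`,
#'   `params`, plus `source`, `target` and the parent `graph`.
#' @export
sample_kl_paths <- function(graph, source, target, l = 5, n_samples = 100,
                            seed = 1, directed = FALSE) {
  stopifnot(inherits(graph, "dc_cellgraph"), n_samples >= 1)
  if (l > graph$k) stop("l must be <= k")
  source <- resolve_cell(graph, source)
  target <- resolve_cell(graph, target)
  n <- graph$n
  by_from <- split(seq_len(nrow(graph$edges)), graph$edges[, "from"])
  paths <- list(); steps <- list(); totals <- numeric(0)
  n_fail <- 0L
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      keep <- unlist(lapply(by_from, function(rows)
        if (length(rows) <= l) rows else rows[sample.int(length(rows), l)]),
        use.names = FALSE)
      sub <- graph$edges[keep, , drop = FALSE]
      adj <- adjacency_list(sub, n, directed = directed)
      p <- if (source == target) source else dijkstra_path(adj, n, source, target)
      if (is.null(p)) {
        n_fail <- n_fail + 1L
      } else {
        st <- if (length(p) > 1)
          unname(graph$dist[cbind(p[-length(p)], p[-1])]) else numeric(0)
        paths[[length(paths) + 1L]] <- p
        steps[[length(steps) + 1L]] <- st
        totals <- c(totals, sum(st))
      }
    }
  })
  if (length(paths) == 0) stop("target unreachable in every sampled subgraph")
  structure(list(paths = paths, step_sizes = steps, totals = totals,
                 n_failures = n_fail, failure_rate = n_fail / n_samples,
                 params = list(k = graph$k, l = l, n_samples = n_samples,
                               seed = seed),
                 source = source, target = target, graph = graph),
            class = "dc_pathensemble")
}

#' @export
print.dc_pathensemble <- function(x, ...) {
  cat(sprintf("Path ensemble %d -> %d: %d paths (%.0f%% of samples failed), k=%d l=%d\n",
              x$source, x$target, length(x$paths), 100 * x$failure_rate,
              x$params$k, x$params$l))
  invisible(x)
}

# Neighborhood sets: for every cell, its n_neighbors nearest cells
# (self included, ties by index).
neighbor_sets <- function(dist_matrix, n_neighbors) {
  n <- nrow(dist_matrix)
  m <- min(n_neighbors, n - 1)
  lapply(seq_len(n), function(i) {
    ord <- order(dist_matrix[i, ], seq_len(n))
    ord <- ord[ord != i]
    c(i, ord[seq_len(m)])
  })
}

#' Per-cell probability of lying near the sampled paths
#'
#' For each successful sample the proximal set is the union, over path
#' nodes, of each node's `n_neighbors`-nearest-cell neighborhood (the node
#' itself included). The returned probability is the fraction of samples in
#' which a cell is proximal. The dual convention — a cell is proximal when a
#' path node is among the *cell's* `n_neighbors` nearest — is available via
#' `direction = "cell_to_path"`.
#'
#' @param ensemble a [sample_kl_paths()] result.
#' @param distances distance provider used for neighborhoods; defaults to
#'   the ensemble's parent graph distances.
#' @param n_neighbors neighborhood size (default 20).
#' @param direction `"path_to_cell"` (default) or `"cell_to_path"`.
#' @return numeric vector of probabilities in \[0, 1\], one per cell.
#' @export
path_proximity <- function(ensemble, distances = NULL, n_neighbors = 20,
                           direction = c("path_to_cell", "cell_to_path")) {
  stopifnot(inherits(ensemble, "dc_pathensemble"), n_neighbors >= 1)
  direction <- match.arg(direction)
  d <- if (is.null(distances)) ensemble$graph$dist else as.matrix(distances)
  nb <- neighbor_sets(d, n_neighbors)
  n <- nrow(d)
  counts <- integer(n)
  for (p in ensemble$paths) {
    prox <- if (direction == "path_to_cell") {
      unique(unlist(nb[p], use.names = FALSE))
    } else {
      which(vapply(nb, function(s) any(p %in% s), logical(1)))
    }
    counts[prox] <- counts[prox] + 1L
  }
  counts / length(ensemble$paths)
}

#' Cluster composition of the path-proximal cells
#'
#' Per successful sample, the fraction of the proximal set (see
#' [path_proximity()]) carrying each cluster label, aggregated as mean and
#' SD across samples. Proportions within a sample sum to 1.
#'
#' @inheritParams path_proximity
#' @param labels per-cell cluster labels.
#' @return list with `per_sample` (samples x labels matrix), `mean`, `sd`.
#' @export
path_membership <- function(ensemble, labels, distances = NULL,
                            n_neighbors = 20) {
  stopifnot(inherits(ensemble, "dc_pathensemble"))
  labels <- as.character(labels)
  d <- if (is.null(distances)) ensemble$graph$dist else as.matrix(distances)
  if (length(labels) != nrow(d)) stop("labels must cover all cells")
  nb <- neighbor_sets(d, n_neighbors)
  lev <- sort(unique(labels))
  per <- vapply(ensemble$paths, function(p) {
    prox <- unique(unlist(nb[p], use.names = FALSE))
    tab <- table(factor(labels[prox], levels = lev))
    as.numeric(tab) / length(prox)
  }, numeric(length(lev)))
  per <- matrix(per, ncol = length(lev), byrow = TRUE,
                dimnames = list(NULL, lev))
  list(per_sample = per, mean = colMeans(per), sd = apply(per, 2, stats::sd))
}

#' Step-size profile of a path, with outlier flags
#'
#' Step distances in path order; a step is flagged as an outlier when it
#' exceeds `median + mad_multiplier * MAD` of the path's steps. An absence
#' of outliers along a trajectory path indicates continuity between the
#' states it connects.
#'
#' @param x a [shortest_path()] result, a [sample_kl_paths()] ensemble
#'   (profiles per path) or a bare numeric vector of step sizes.
#' @param mad_multiplier outlier rule multiplier (default 5).
#' @return `data.frame(step, size, outlier)` (or a list of them for an
#'   ensemble). A single-node path yields an empty profile.
#' @export
step_size_profile <- function(x, mad_multiplier = 5) {
  profile_one <- function(steps) {
    if (length(steps) == 0)
      return(data.frame(step = integer(0), size = numeric(0),
                        outlier = logical(0)))
    thr <- stats::median(steps) + mad_multiplier * stats::mad(steps)
    data.frame(step = seq_along(steps), size = steps, outlier = steps > thr)
  }
  if (inherits(x, "dc_pathensemble")) return(lapply(x$step_sizes, profile_one))
  if (is.list(x) && !is.null(x$step_sizes)) return(profile_one(x$step_sizes))
  profile_one(as.numeric(x))
}
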