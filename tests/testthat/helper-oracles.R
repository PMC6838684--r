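# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# 1-D optimal transport cost between two equal-total empirical measures by
# greedy north-west-corner matching on the sorted samples — the provably
# optimal solution of the transport linear program for convex 1-D costs.
emd_transport_oracle <- function(x, y) {
  xs <- sort(x); ys <- sort(y)
  wx <- rep(1 / length(x), length(x))
  wy <- rep(1 / length(y), length(y))
  i <- 1; j <- 1; cost <- 0
  while (i <= length(xs) && j <= length(ys)) {
    m <- min(wx[i], wy[j])
    cost <- cost + m * abs(xs[i] - ys[j])
    wx[i] <- wx[i] - m
    wy[j] <- wy[j] - m
    if (wx[i] <= 1e-15) i <- i + 1
    if (wy[j] <= 1e-15) j <- j + 1
  }
  cost
}

# AUC by explicit all-pairs counting with half-credit ties.
auc_pairs_oracle <- function(x, y) {
  wins <- 0
  for (xi in x) wins <- wins + sum(xi > y) + 0.5 * sum(xi == y)
  wins / (length(x) * length(y))
}

# Adjusted Rand index by classifying every unordered pair of cells as
# together/apart in each partition.
ari_pairs_oracle <- function(p1, p2) {
  n <- length(p1)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  max_index <- ((a + b) + (a + c_)) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}

# Shortest path total length by exhaustive depth-first enumeration of all
# simple paths (undirected weighted edge list), feasible for <= 12 nodes.
brute_shortest_path <- function(edges, n, source, target) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]; w <- edges[r, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  best <- Inf
  dfs <- function(u, visited, len) {
    if (len >= best) return()
    if (u == target) { best <<- len; return() }
    e <- adj[[u]]
    if (is.null(e)) return()
    for (r in seq_len(nrow(e))) {
      v <- e[r, 1]
      if (!visited[v]) {
        visited[v] <- TRUE
        dfs(v, visited, len + e[r, 2])
        visited[v] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n); vis[source] <- TRUE
  dfs(source, vis, 0)
  unname(best)
}

# Exact Mann-Whitney U null distribution by the counting recurrence
# c(n, m, u) = c(n-1, m, u-m) + c(n, m-1, u); returns P(U = 0..n*m).
mw_exact_distribution <- function(n, m) {
  # f[[i+1]][[j+1]] = counts over u for group sizes i, j
  f <- matrix(list(), n + 1, m + 1)
  for (j in 0:m) f[[1, j + 1]] <- 1          # n = 0: only u = 0
  for (i in 0:n) f[[i + 1, 1]] <- 1          # m = 0
  for (i in 1:n) for (j in 1:m) {
    a <- f[[i, j + 1]]                        # last x-element placed first: u += j
    a <- c(rep(0, j), a)
    b <- f[[i + 1, j]]                        # last y-element placed first
    len <- max(length(a), length(b))
    f[[i + 1, j + 1]] <- c(a, rep(0, len - length(a))) +
      c(b, rep(0, len - length(b)))
  }
  counts <- f[[n + 1, m + 1]]
  counts <- c(counts, rep(0, n * m + 1 - length(counts)))
  counts / choose(n + m, n)
}

# Two-sided exact Mann-Whitney p-value (tie-free data), doubling the smaller
# tail and capping at 1 — the convention of the exact two-sample test.
mw_exact_p <- function(u, n, m) {
  d <- mw_exact_distribution(n, m)
  lower <- sum(d[seq_len(u + 1)])
  upper <- sum(d[(u + 1):(n * m + 1)])
  min(1, 2 * min(lower, upper))
}

# Exact two-sample KS p-value by enumerating all group assignments of the
# pooled sample (tie-free), feasible for small groups.
ks_exact_p_oracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); m <- length(y)
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  d_obs <- ks_stat(x, y)
  combs <- utils::combn(n + m, n)
  hits <- 0
  for (k in seq_len(ncol(combs))) {
    a <- pool[combs[, k]]; b <- pool[-combs[, k]]
    if (ks_stat(a, b) >= d_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combs)
}

# Benjamini-Hochberg by the direct sort-based definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force re-application of the peak classification rules, written as
# plain loops over the annotation tables.
annotate_oracle <- function(atlas, gm, promoter_radius = 2000,
                            max_gene_distance = 50000) {
  genes <- gm$genes
  tss <- gm$tss
  exons <- gm$exons
  out <- character(nrow(atlas))
  for (i in seq_len(nrow(atlas))) {
    ws <- atlas$wstart[i]; we <- atlas$wend[i]; ch <- atlas$chrom[i]
    sm <- atlas$summit[i]
    is_promoter <- FALSE
    for (r in seq_len(nrow(tss))) {
      g <- genes[genes$gene_id == tss$gene_id[r], ]
      if (g$chrom == ch && abs(sm - tss$pos[r]) <= promoter_radius)
        is_promoter <- TRUE
    }
    is_exonic <- FALSE
    for (r in seq_len(nrow(exons))) {
      g <- genes[genes$gene_id == exons$gene_id[r], ]
      if (g$chrom == ch && ws < exons$end[r] && exons$start[r] < we)
        is_exonic <- TRUE
    }
    is_intronic <- FALSE
    is_intergenic <- FALSE
    for (r in seq_len(nrow(genes))) {
      if (genes$chrom[r] != ch) next
      if (ws < genes$end[r] && genes$start[r] < we) is_intronic <- TRUE
      gap <- max(0, genes$start[r] - we, ws - genes$end[r])
      if (gap <= max_gene_distance) is_intergenic <- TRUE
    }
    out[i] <- if (is_promoter) "promoter" else if (is_exonic) "exonic" else
      if (is_intronic) "intronic" else if (is_intergenic) "intergenic" else
        "unclassified"
  }
  out
}

# Brute-force exact motif p-values: enumerate all 4^L sequences, score with
# the same discretization, and tabulate the background-weighted tail.
motif_pvalue_oracle <- function(motif, score_int, bin = 1e-3) {
  wi <- dc2scape:::motif_int_weights(motif, bin)[1:4, , drop = FALSE]
  L <- ncol(wi)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    scores[r] <- sum(wi[cbind(grid[r, ], seq_len(L))])
    probs[r] <- prod(motif$background[grid[r, ]])
  }
  sum(probs[scores >= score_int])
}

# Run an expression under a fixed seed (test-local RNG hygiene).
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
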