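# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Benjamini-Hochberg adjustment (thin wrapper, kept for a single entry point).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Column z-score with zero-variance (or single-observation) columns mapped
# to 0.
zscore_cols <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  out <- sweep(m, 2, mu)
  nz <- !is.na(sdv) & sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sdv[nz], `/`)
  out[, !nz] <- 0
  out
}
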