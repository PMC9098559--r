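# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. All exported stochastic
# operations funnel their draws through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of sub-seeds from one master seed; keeps independent
# operations decoupled while staying reproducible and < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# argmax with ties broken toward the lowest index; all-zero rows get NA.
argmax_row <- function(m) {
  lab <- max.col(m, ties.method = "first")
  lab[rowSums(abs(m)) == 0] <- NA_integer_
  lab
}

# Repair a symmetric matrix to the nearest valid correlation matrix by
# eigenvalue clipping followed by re-normalization to unit diagonal.
repair_correlation <- function(M, tol = 1e-8) {
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  R <- ee$vectors %*% (vals * t(ee$vectors))
  d <- diag(R)
  if (any(d <= 0)) {
    stop("correlation repair failed: zero diagonal after eigenvalue clipping")
  }
  R <- R / sqrt(outer(d, d))
  R <- (R + t(R)) / 2
  diag(R) <- 1
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
    stop("correlation repair failed: matrix not PSD after renormalization")
  }
  R
}

# Best one-to-one matching of columns of A to columns of B maximizing the
# summed Pearson correlation (Hungarian assignment). Returns the
# permutation `perm` with B[, perm[k]] matched to A[, k], and the matched
# correlations.
match_columns <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  cmat <- suppressWarnings(stats::cor(A, B))
  cmat[!is.finite(cmat)] <- 0
  perm <- as.integer(clue::solve_LSAP(cmat - min(cmat) + 1, maximum = TRUE))
  list(perm = perm, correlations = cmat[cbind(seq_len(ncol(A)), perm)])
}

# Column-wise max normalization: each column scaled to max 1 (zero
# columns left untouched). Returns the matrix and the scales used.
max_normalize <- function(V) {
  cmax <- apply(V, 2L, max)
  scl <- ifelse(cmax > 0, cmax, 1)
  list(V = sweep(V, 2L, scl, "/"), scales = scl)
}

# Moran's-I style spatial autocorrelation over a neighbour structure:
# mean product of standardized values across all adjacent pairs.
neighbor_autocorrelation <- function(values, neighbors) {
  z <- as.numeric(scale(values))
  num <- 0
  npairs <- 0L
  for (v in seq_along(neighbors)) {
    for (w in neighbors[[v]]) {
      if (w > v) {
        num <- num + z[v] * z[w]
        npairs <- npairs + 1L
      }
    }
  }
  num / npairs
}
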