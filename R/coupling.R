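#' Edge-level between-network coupling
#'
#' Cell (A, B), A != B, is the mean Pearson correlation over all
#' cross-network vertex pairs (a in A, b in B); correlations are
#' averaged raw (no Fisher transform). The diagonal stores the mean
#' within-network pairwise correlation (informational). Networks with no
#' assigned vertices produce NA cells.
#'
#' @param X T x S timeseries matrix.
#' @param labels per-vertex network labels (1..K, NA allowed).
#' @param K number of networks; defaults to `max(labels)`.
#' @return K x K symmetric matrix.
#' @export
edgeCoupling <- function(X, labels, K = max(labels, na.rm = TRUE)) {
  C <- vertex_correlations(X)
  G <- label_indicator(labels, K, nrow(C))
  nk <- colSums(G)
  Ssum <- t(G) %*% C %*% G
  E <- matrix(NA_real_, K, K)
  for (A in seq_len(K)) {
    for (B in seq_len(K)) {
      if (nk[A] == 0 || nk[B] == 0) next
      if (A == B) {
        if (nk[A] > 1) {
          E[A, A] <- (Ssum[A, A] - nk[A]) / (nk[A] * (nk[A] - 1))
        }
      } else {
        E[A, B] <- Ssum[A, B] / (nk[A] * nk[B])
      }
    }
  }
  E
}

# Pearson correlation over vertices with zero-variance columns flagged 0.
vertex_correlations <- function(X) {
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

label_indicator <- function(labels, K, S) {
  stopifnot(length(labels) == S)
  G <- matrix(0, S, K)
  ok <- !is.na(labels)
  G[cbind(which(ok), labels[ok])] <- 1
  G
}

#' Network-level between-network coupling
#'
#' Each network's mean coupling to all other networks: the mean of its
#' off-diagonal row in the edge matrix, ignoring missing cells.
#'
#' @param edge_matrix K x K matrix from [edgeCoupling()].
#' @return length-K numeric vector (NA for empty networks).
#' @export
networkCoupling <- function(edge_matrix) {
  off <- edge_matrix
  diag(off) <- NA
  out <- rowMeans(off, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Vertex-level between-network coupling
#'
#' For a vertex v in network A: the mean Pearson correlation of v's
#' timeseries with every vertex outside A.
#'
#' @param X T x S timeseries matrix.
#' @param labels per-vertex network labels.
#' @return length-S numeric vector (NA for unassigned vertices).
#' @export
vertexCoupling <- function(X, labels) {
  C <- vertex_correlations(X)
  S <- ncol(X)
  out <- rep(NA_real_, S)
  tot <- rowSums(C) - 1           # exclude self-correlation
  for (v in seq_len(S)) {
    if (is.na(labels[v])) next
    own <- which(labels == labels[v])
    n_out <- S - length(own)
    if (n_out == 0) next
    out[v] <- (tot[v] - (sum(C[v, own]) - 1)) / n_out
  }
  out
}

#' All coupling levels for one subject at one scale
#'
#' Convenience constructor computing the edge matrix, network vector and
#' vertex vector from a subject's timeseries and personalized hard
#' partition.
#'
#' @param X T x S timeseries matrix.
#' @param labels per-vertex labels from [hardPartition()].
#' @param K scale.
#' @param subject_id character id.
#' @return a [CouplingSet-class].
#' @export
computeCoupling <- function(X, labels, K = max(labels, na.rm = TRUE),
                            subject_id = "subject") {
  E <- edgeCoupling(X, labels, K)
  new("CouplingSet", subjectId = subject_id, scale = as.integer(K),
      edgeMatrix = E, networkVector = networkCoupling(E),
      vertexVector = vertexCoupling(X, labels))
}

#' Network positions on the functional hierarchy
#'
#' The hierarchy value of a network is the mean per-vertex hierarchy
#' over the group-consensus hard partition; the hierarchical distance of
#' an edge is the absolute difference of its two networks' values.
#'
#' @param group_partition per-vertex labels of the group atlas.
#' @param hierarchy_map per-vertex hierarchy values.
#' @return list with `network` (length-K means) and `edge_distance`
#'   (K x K absolute-difference matrix).
#' @export
networkHierarchyValues <- function(group_partition, hierarchy_map) {
  ks <- seq_len(max(group_partition, na.rm = TRUE))
  h <- vapply(ks, function(k) {
    mean(hierarchy_map[which(group_partition == k)])
  }, numeric(1))
  list(network = h, edge_distance = abs(outer(h, h, "-")))
}

#' Mean Euclidean distance between network vertex sets
#'
#' For each network pair, the mean pairwise 3D Euclidean distance
#' between their member vertex coordinates; a geometric covariate used
#' to check that hierarchical-distance effects are not mere spatial
#' proximity effects.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param group_partition per-vertex labels.
#' @return K x K symmetric matrix (diagonal: mean within-network pair
#'   distance).
#' @export
euclideanEdgeDistance <- function(mesh, group_partition) {
  co <- vertexCoords(mesh)
  K <- max(group_partition, na.rm = TRUE)
  idx <- lapply(seq_len(K), function(k) which(group_partition == k))
  out <- matrix(NA_real_, K, K)
  for (A in seq_len(K)) {
    for (B in A:K) {
      if (length(idx[[A]]) == 0 || length(idx[[B]]) == 0) next
      coA <- co[idx[[A]], , drop = FALSE]
      coB <- co[idx[[B]], , drop = FALSE]
      d2 <- outer(rowSums(coA^2), rowSums(coB^2), "+") -
        2 * coA %*% t(coB)
      dd <- sqrt(pmax(d2, 0))
      if (A == B) {
        if (length(idx[[A]]) > 1) {
          out[A, A] <- mean(dd[upper.tri(dd)])
        } else {
          out[A, A] <- 0
        }
      } else {
        out[A, B] <- out[B, A] <- mean(dd)
      }
    }
  }
  out
}

#' Topographic variability (MAD) map
#'
#' Per vertex and network, the median absolute deviation of loadings
#' across subjects (no consistency constant), averaged across the K
#' networks to yield one value per vertex; optionally z-scored within
#' the scale.
#'
#' @param Vs list (>= 3 subjects) of S x K loading matrices.
#' @param zscore also return the z-scored map.
#' @return list with `mad` (length-S) and, if requested, `z`.
#' @export
madMap <- function(Vs, zscore = TRUE) {
  if (length(Vs) < 3L) stop("MAD needs at least 3 subjects")
  S <- nrow(Vs[[1L]]); K <- ncol(Vs[[1L]])
  arr <- array(unlist(Vs), dim = c(S, K, length(Vs)))
  per_net <- apply(arr, c(1L, 2L), function(x) {
    stats::median(abs(x - stats::median(x)))
  })
  m <- rowMeans(per_net)
  out <- list(mad = m)
  if (zscore) out$z <- as.numeric(scale(m))
  out
}
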