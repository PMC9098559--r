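#' Bootstrap group-level NMF decompositions
#'
#' Repeatedly selects a random subject subset, temporally concatenates
#' their (preprocessed) timeseries, and fits a group NMF with random
#' initialization. The replicate atlases are later fused by
#' [fuseAtlases()] into one robust group atlas. Desk-scale defaults use
#' smaller subsets and fewer replicates than a full cohort study would
#' (the study-scale convention is 100 subjects per subset, 50 replicates).
#'
#' @param Xs list of preprocessed T x S subject matrices.
#' @param L graph Laplacian used for the pooled fits (e.g. built from the
#'   concatenation of all subjects, or the mesh-average affinity).
#' @param config from [nmfConfig()].
#' @param n_subset subjects per bootstrap draw.
#' @param n_reps number of bootstrap replicates (>= 2).
#' @param seed integer RNG seed controlling subset draws and inits.
#' @return list of `n_reps` S x K loading matrices.
#' @export
bootstrapGroupAtlases <- function(Xs, L, config, n_subset = 20L,
                                  n_reps = 10L, seed = 1L) {
  n <- length(Xs)
  if (n_subset > n) stop("n_subset exceeds the number of subjects")
  if (n_reps < 2L) stop("atlas fusion needs at least 2 replicates")
  subset_seeds <- derive_seeds(seed, n_reps)
  lapply(seq_len(n_reps), function(r) {
    idx <- with_seed(subset_seeds[r], sample.int(n, n_subset))
    Xcat <- do.call(rbind, Xs[idx])
    cfg_r <- config
    cfg_r$seed <- subset_seeds[r] %% .Machine$integer.max
    fitGroupNmf(Xcat, L, cfg_r)$V
  })
}

#' Pairwise network similarity of stacked atlases
#'
#' Distances between all stacked networks are \eqn{d_{ij} = 1 -
#' corr(V_i, V_j)} over vertices; similarities are the Gaussian kernel
#' \eqn{S_{ij} = \exp(-d_{ij}^2 / \sigma^2)} with \eqn{\sigma} the
#' median off-diagonal distance.
#'
#' @param V_stacked S x (reps * K) matrix of stacked network loadings.
#' @return list with `d` (distance matrix), `sigma`, and `S_sim`.
#' @export
networkSimilarity <- function(V_stacked) {
  cc <- suppressWarnings(stats::cor(V_stacked))
  cc[!is.finite(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  sigma <- stats::median(d[upper.tri(d)])
  if (sigma <= 0) sigma <- 1e-8
  S_sim <- exp(-d^2 / sigma^2)
  list(d = d, sigma = sigma, S_sim = S_sim)
}

# Normalized-cut spectral clustering of a similarity matrix into K
# clusters: leading K eigenvectors of D^{-1/2} S D^{-1/2}, row-normalized,
# then seeded k-means.
spectral_cluster <- function(S_sim, K, seed = 1L) {
  deg <- rowSums(S_sim)
  dd <- 1 / sqrt(pmax(deg, 1e-12))
  M <- S_sim * outer(dd, dd)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  E <- ev$vectors[, seq_len(K), drop = FALSE]
  rn <- sqrt(rowSums(E^2))
  E <- E / pmax(rn, 1e-12)
  km <- with_seed(seed, stats::kmeans(E, centers = K, nstart = 20L,
                                      iter.max = 100L))
  km$cluster
}

#' Fuse bootstrap atlases by spectral clustering
#'
#' Stacks the replicate networks, applies normalized-cut spectral
#' clustering of the Gaussian network similarity into K clusters, and
#' selects per cluster the network with the highest total similarity to
#' its cluster co-members (self-similarity excluded) as the
#' representative. Representatives are ordered for determinism by their
#' first-occurrence position in the stack.
#'
#' @param atlases list of S x K loading matrices from
#'   [bootstrapGroupAtlases()].
#' @param K the scale.
#' @param seed seed for the spectral k-means stage.
#' @return a [GroupAtlas-class].
#' @export
fuseAtlases <- function(atlases, K, seed = 1L) {
  V_stacked <- do.call(cbind, atlases)
  sim <- networkSimilarity(V_stacked)
  cl <- NULL
  attempt_seeds <- derive_seeds(seed, 5L)
  for (a in seq_len(5L)) {
    cand <- spectral_cluster(sim$S_sim, K, seed = attempt_seeds[a])
    if (length(unique(cand)) == K) { cl <- cand; break }
  }
  if (is.null(cl)) stop("spectral clustering produced an empty cluster in 5 attempts")
  reps <- vapply(seq_len(K), function(k) {
    members <- which(cl == k)
    score <- vapply(members, function(m) {
      sum(sim$S_sim[m, setdiff(members, m)])
    }, numeric(1))
    members[which.max(score)]
  }, integer(1))
  reps <- reps[order(reps)]
  V <- max_normalize(V_stacked[, reps, drop = FALSE])$V
  new("GroupAtlas", loadings = V, scale = as.integer(K),
      provenance = as.integer(reps))
}

#' Personalize the group atlas to one subject
#'
#' Runs the joint regularized NMF for the single subject, initialized at
#' the group-consensus atlas so the returned networks stay in atlas
#' order, with the locality penalty from the subject's own affinity
#' graph and the consensus term acting as a per-column sparsity anchor.
#' With `max_iter = 0` the initialization is returned unchanged.
#'
#' @param X preprocessed T x S subject matrix.
#' @param L subject Laplacian from [buildAffinity()].
#' @param atlas a [GroupAtlas-class].
#' @param config from [nmfConfig()]; its K must match the atlas scale.
#' @return S x K personalized loading matrix (nonnegative, column max 1).
#' @export
personalizeNetworks <- function(X, L, atlas, config) {
  stopifnot(config$K == networkScale(atlas))
  if (config$max_iter == 0L) return(atlasLoadings(atlas))
  fit <- fitMultisubjectNmf(list(X), list(L), config,
                            init_V = atlasLoadings(atlas))
  fit[[1L]]$V
}

#' Hard network partition from soft loadings
#'
#' Assigns each vertex to its highest-loading network; ties break toward
#' the lowest network index, and all-zero rows are left unassigned (NA).
#'
#' @param V S x K loading matrix.
#' @return integer vector of per-vertex labels in 1..K (NA = unassigned).
#' @export
hardPartition <- function(V) {
  argmax_row(V)
}

#' Nestedness of a fine-scale partition within the K = 2 partition
#'
#' For each network at scale K, the parent is the K = 2 label holding
#' the plurality of its vertices and the overlap fraction is that
#' plurality share. The summary gives the percentage of networks falling
#' in each coarse parent. Plurality ties break toward the lower label.
#'
#' @param partition_k2 per-vertex labels at K = 2.
#' @param partition_K per-vertex labels at scale K.
#' @return list with `per_network` (data.frame: network, parent,
#'   overlap) and `summary` (percent of networks per parent).
#' @export
nestednessVsK2 <- function(partition_k2, partition_K) {
  ks <- sort(unique(partition_K[!is.na(partition_K)]))
  per <- lapply(ks, function(k) {
    parents <- partition_k2[which(partition_K == k)]
    tab <- table(factor(parents, levels = sort(unique(partition_k2))))
    parent <- as.integer(names(tab)[which.max(tab)])  # ties -> lower label
    data.frame(network = k, parent = parent,
               overlap = max(tab) / sum(tab))
  })
  per <- do.call(rbind, per)
  pct <- 100 * as.numeric(table(factor(per$parent,
           levels = sort(unique(partition_k2))))) / nrow(per)
  names(pct) <- sort(unique(partition_k2))
  list(per_network = per, summary = pct)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model, computed from
#' the contingency table; 1 for identical partitions, near 0 for
#' independent ones, possibly negative for worse-than-chance agreement.
#'
#' @param labelsA,labelsB integer label vectors of equal length; pairs
#'   with an NA in either are dropped.
#' @return scalar ARI in \[-1, 1\].
#' @export
adjustedRand <- function(labelsA, labelsB) {
  keep <- !is.na(labelsA) & !is.na(labelsB)
  a <- labelsA[keep]; b <- labelsB[keep]
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

#' Match network columns between two loading matrices
#'
#' Best one-to-one assignment (Hungarian algorithm) of the columns of
#' `B` to the columns of `A`, maximizing summed Pearson correlation.
#' Used as a diagnostic for atlas/personalization correspondence; the
#' optimization itself keeps atlas order by initialization.
#'
#' @param A,B S x K loading matrices.
#' @return list with `perm` (B column matched to each A column) and
#'   `correlations` (the matched correlation per A column).
#' @export
matchNetworks <- function(A, B) {
  match_columns(A, B)
}
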