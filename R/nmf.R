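#' NMF solver configuration
#'
#' @param K number of networks (scale), K >= 2.
#' @param alpha group-consensus ("sparsity") weight; enters
#'   \eqn{\lambda_c = \alpha \, n T / K}. Default 1.
#' @param beta locality weight; enters \eqn{\lambda_M = \beta\, T /(K
#'   n_m)} with \eqn{n_m} the mean vertex neighbour count. Default 10.
#' @param max_iter maximum alternating update iterations.
#' @param tol relative objective-change stopping threshold.
#' @param seed seed for random initialization.
#' @return a named list.
#' @export
nmfConfig <- function(K, alpha = 1, beta = 10, max_iter = 300L,
                      tol = 1e-6, seed = 1L) {
  stopifnot(K >= 2, alpha >= 0, beta >= 0, tol > 0, max_iter >= 0)
  list(K = as.integer(K), alpha = alpha, beta = beta,
       max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed))
}

#' Shift and scale vertex timeseries for NMF
#'
#' Per vertex: subtract the minimum, then divide by the maximum, so all
#' values lie in \[0, 1\] as required by the nonnegative factorization.
#' Constant vertices map to all-zeros.
#'
#' @param X T x S timeseries matrix (time x vertex).
#' @return T x S matrix in \[0, 1\].
#' @export
preprocessForNmf <- function(X) {
  if (!all(is.finite(X))) stop("timeseries contains non-finite values")
  if (nrow(X) < 2L) stop("need at least 2 timepoints")
  mins <- apply(X, 2L, min)
  X <- sweep(X, 2L, mins)
  maxs <- apply(X, 2L, max)
  maxs[maxs == 0] <- 1   # constant vertices become all-zero
  sweep(X, 2L, maxs, "/")
}

#' Spatial affinity graph and Laplacian
#'
#' For every pair of spatially connected (mesh-neighbour) vertices a, b
#' the affinity is \eqn{(1 + corr(X_a, X_b))/2}; all other pairs are 0,
#' so W is sparse. The Laplacian is \eqn{L = D - W} with D the degree
#' diagonal. Zero-variance vertices get affinity 0.5 on their edges
#' (correlation taken as 0, the uninformative limit).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param X T x S timeseries matrix.
#' @return list with sparse matrices `W`, `D`, `L`.
#' @export
buildAffinity <- function(mesh, X) {
  S <- nVertices(mesh)
  stopifnot(ncol(X) == S)
  nb <- neighborLists(mesh)
  ii <- rep.int(seq_len(S), lengths(nb))
  jj <- unlist(nb, use.names = FALSE)
  keep <- ii < jj
  ii <- ii[keep]; jj <- jj[keep]
  Xs <- scale(X)               # zero-variance vertices become NaN columns
  Xs[, !is.finite(colSums(Xs))] <- 0
  Tm1 <- nrow(X) - 1L
  rr <- colSums(Xs[, ii, drop = FALSE] * Xs[, jj, drop = FALSE]) / Tm1
  w <- (1 + rr) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(w, w),
                            dims = c(S, S))
  D <- Matrix::Diagonal(x = Matrix::rowSums(W))
  list(W = W, D = D, L = D - W)
}

#' Group-consensus penalty
#'
#' The L2,1-ratio group-sparsity term over the stacked subject loadings:
#' \deqn{R_c = \sum_k \frac{\sum_s (\sum_i (V^i_{s,k})^2)^{1/2}}
#'   {(\sum_s \sum_i (V^i_{s,k})^2)^{1/2}}.}
#' Scale-invariant per network; an all-zero network column contributes 0.
#'
#' @param Vs list of S x K subject loading matrices.
#' @return scalar penalty value.
#' @export
consensusPenalty <- function(Vs) {
  K <- ncol(Vs[[1L]])
  stopifnot(all(vapply(Vs, ncol, 1L) == K),
            all(vapply(Vs, nrow, 1L) == nrow(Vs[[1L]])))
  total <- 0
  for (k in seq_len(K)) {
    sq <- Reduce(`+`, lapply(Vs, function(V) V[, k]^2))
    b <- sqrt(sum(sq))
    if (b > 0) total <- total + sum(sqrt(sq)) / b
  }
  total
}

#' Data-locality (graph smoothness) penalty
#'
#' \eqn{R_M = Tr(V' L V)}, equal to the affinity-weighted sum of squared
#' loading differences across mesh edges; nonnegative by PSD of L.
#'
#' @param V S x K loading matrix.
#' @param L S x S graph Laplacian.
#' @return scalar penalty value.
#' @export
localityPenalty <- function(V, L) {
  sum(V * as.matrix(L %*% V))
}

#' Regularization weights from the scaling rules
#'
#' \eqn{\lambda_c = \alpha \, n T / K} (consensus) and
#' \eqn{\lambda_M = \beta \, T / (K n_m)} (locality), where n is the
#' number of subjects, T the timepoints per subject and \eqn{n_m} the
#' (mean) number of neighbouring vertices.
#'
#' @param config from [nmfConfig()].
#' @param n number of subjects in the joint fit.
#' @param T_len timepoints per subject.
#' @param n_m mean vertex neighbour count of the mesh.
#' @return list with `lambda_M` and `lambda_c`.
#' @export
regularizationWeights <- function(config, n, T_len, n_m) {
  list(lambda_M = config$beta * T_len / (config$K * n_m),
       lambda_c = config$alpha * n * T_len / config$K)
}

#' Joint NMF objective
#'
#' Sum of per-subject squared-Frobenius reconstruction errors plus the
#' weighted locality and consensus penalties:
#' \deqn{\sum_i \|X^i - U^i (V^i)'\|_F^2 + \lambda_M \sum_i Tr((V^i)' L^i
#'   V^i) + \lambda_c R_c.}
#'
#' @param Xs,Us,Vs,Ls lists (one entry per subject) of data, course,
#'   loading and Laplacian matrices.
#' @param lambda_M,lambda_c penalty weights.
#' @return scalar objective value.
#' @export
nmfObjective <- function(Xs, Us, Vs, Ls, lambda_M, lambda_c) {
  recon <- sum(vapply(seq_along(Xs), function(i) {
    sum((Xs[[i]] - Us[[i]] %*% t(Vs[[i]]))^2)
  }, numeric(1)))
  loc <- sum(vapply(seq_along(Vs), function(i) {
    localityPenalty(Vs[[i]], Ls[[i]])
  }, numeric(1)))
  recon + lambda_M * loc + lambda_c * consensusPenalty(Vs)
}

# One multiplicative update sweep for a single subject.
# U <- U * (XV) / (U V'V); V gains the graph term (lambda_M W V in the
# numerator, lambda_M D V in the denominator) and the split consensus
# subgradient (cneg numerator, cpos denominator).
mu_update <- function(X, U, V, W, D, lambda_M, cneg = 0, cpos = 0,
                      eps = 1e-10) {
  U <- U * (X %*% V) / (U %*% crossprod(V) + eps)
  num <- crossprod(X, U) + cneg
  den <- V %*% crossprod(U) + cpos + eps
  if (lambda_M > 0) {
    num <- num + lambda_M * as.matrix(W %*% V)
    den <- den + lambda_M * as.matrix(D %*% V)
  }
  V <- V * num / den
  list(U = U, V = V)
}

# Split consensus-gradient contributions for subject i given the stacked
# column statistics. Returns the numerator (negative gradient part) and
# denominator (positive part) matrices.
consensus_parts <- function(V, sq_all, lambda_c, eps = 1e-10) {
  a <- sqrt(sq_all)                       # S x K, stacked column norms
  b <- sqrt(colSums(sq_all))              # per-network Frobenius norm
  A <- colSums(a)
  b <- pmax(b, eps)
  a <- pmax(a, eps)
  cneg <- lambda_c * sweep(V, 2L, A / b^3, "*")
  cpos <- lambda_c * V / sweep(a, 2L, b, "*")
  list(cneg = cneg, cpos = cpos)
}

#' Fit group-level graph-regularized NMF
#'
#' Alternating nonnegativity-preserving multiplicative updates of the
#' time courses U (T x K) and loadings V (S x K) minimizing
#' \eqn{\|X - U V'\|_F^2 + \lambda_M Tr(V' L V) + \lambda_c R_c} on
#' pooled (concatenated) timepoints. For the single pooled V the
#' consensus term reduces to the per-column L1/L2 sparsity ratio, which
#' is what the sparsity weight \eqn{\alpha} controls (it keeps network
#' loadings parts-based rather than diffuse); set `alpha = 0` to
#' disable. A monotonicity safeguard halves any update step that would
#' increase the objective, so the recorded objective trace is
#' non-increasing. At convergence each V column is rescaled to max 1
#' with the inverse scale folded into U, leaving U V' unchanged.
#'
#' @param X nonnegative T x S matrix (preprocessed, pooled timepoints).
#' @param L S x S graph Laplacian (see [buildAffinity()]).
#' @param config from [nmfConfig()].
#' @param init optional list(U, V) initial factors; random if NULL.
#' @return list with `U`, `V`, `objective` (trace over iterations),
#'   `iterations`.
#' @export
fitGroupNmf <- function(X, L, config, init = NULL) {
  if (any(X < 0)) stop("X must be nonnegative; run preprocessForNmf first")
  K <- config$K
  if (K > min(dim(X))) stop("K exceeds min(timepoints, vertices)")
  S <- ncol(X); T_len <- nrow(X)
  n_m <- mean(Matrix::rowSums(L != 0) - 1)
  lambda_M <- if (n_m > 0) config$beta * T_len / (K * n_m) else 0
  lambda_c <- config$alpha * T_len / K
  W <- -L; diag(W) <- 0
  D <- Matrix::Diagonal(x = Matrix::diag(L))

  if (is.null(init)) {
    scl <- sqrt(max(mean(X), 1e-6) / K)
    init <- with_seed(config$seed, {
      list(U = matrix(stats::runif(T_len * K), T_len, K) * scl,
           V = matrix(stats::runif(S * K), S, K) * scl)
    })
  }
  U <- init$U; V <- pmax(init$V, 1e-8)
  obj <- nmfObjective(list(X), list(U), list(V), list(L), lambda_M, lambda_c)
  trace <- obj
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    cp <- consensus_parts(V, V^2, lambda_c)
    cand <- mu_update(X, U, V, W, D, lambda_M, cp$cneg, cp$cpos)
    upd <- cand
    new_obj <- nmfObjective(list(X), list(upd$U), list(upd$V), list(L),
                            lambda_M, lambda_c)
    theta <- 1
    while (new_obj > obj * (1 + 1e-12) && theta > 2^-12) {
      theta <- theta / 2
      upd$U <- (1 - theta) * U + theta * cand$U
      upd$V <- (1 - theta) * V + theta * cand$V
      new_obj <- nmfObjective(list(X), list(upd$U), list(upd$V), list(L),
                              lambda_M, lambda_c)
    }
    if (new_obj > obj * (1 + 1e-12)) break   # stalled; keep previous state
    U <- upd$U; V <- upd$V
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) < config$tol * max(obj, 1e-12)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  nrm <- max_normalize(V)
  list(U = sweep(U, 2L, nrm$scales, "*"), V = nrm$V,
       objective = trace, iterations = iter)
}

#' Fit the joint multi-subject regularized NMF
#'
#' Optimizes the full joint model over all subjects: per-subject
#' reconstruction, per-subject locality penalties, and the
#' group-consensus penalty coupling subjects (the L2,1-ratio term, whose
#' split subgradient enters the multiplicative V updates). Each subject's
#' V is initialized at the group atlas (`init_V`), preserving network
#' correspondence across subjects. A monotonicity safeguard halves steps
#' that would increase the objective.
#'
#' @param Xs list of nonnegative T x S matrices, all with the same S.
#' @param Ls list of per-subject Laplacians.
#' @param config from [nmfConfig()].
#' @param init_V S x K initialization (a group atlas loading matrix), or
#'   a list of per-subject initializations.
#' @return list of per-subject lists `list(U, V)`, with attributes
#'   `objective` (trace) and `iterations`.
#' @export
fitMultisubjectNmf <- function(Xs, Ls, config, init_V) {
  n <- length(Xs)
  S <- ncol(Xs[[1L]])
  if (!all(vapply(Xs, ncol, 1L) == S)) {
    stop("all subjects must share the same vertex count S")
  }
  if (any(vapply(Xs, function(X) any(X < 0), logical(1)))) {
    stop("all Xs must be nonnegative; run preprocessForNmf first")
  }
  K <- config$K
  T_len <- nrow(Xs[[1L]])
  n_m <- mean(Matrix::rowSums(Ls[[1L]] != 0) - 1)
  wts <- regularizationWeights(config, n, T_len, n_m)
  lambda_M <- wts$lambda_M; lambda_c <- wts$lambda_c

  Vs <- if (is.list(init_V)) {
    lapply(init_V, function(V) pmax(V, 1e-8))
  } else {
    replicate(n, pmax(init_V, 1e-8), simplify = FALSE)
  }
  Ws <- lapply(Ls, function(L) { W <- -L; diag(W) <- 0; W })
  Ds <- lapply(Ls, function(L) Matrix::Diagonal(x = Matrix::diag(L)))
  # warm-start courses by ridge projection onto the initial loadings
  Us <- lapply(seq_len(n), function(i) {
    G <- crossprod(Vs[[i]]) + diag(1e-8, K)
    pmax(Xs[[i]] %*% Vs[[i]] %*% solve(G), 1e-8)
  })

  obj <- nmfObjective(Xs, Us, Vs, Ls, lambda_M, lambda_c)
  trace <- obj
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    sq_all <- Reduce(`+`, lapply(Vs, function(V) V^2))
    newU <- Us; newV <- Vs
    for (i in seq_len(n)) {
      cp <- consensus_parts(Vs[[i]], sq_all, lambda_c)
      upd <- mu_update(Xs[[i]], Us[[i]], Vs[[i]], Ws[[i]], Ds[[i]],
                       lambda_M, cp$cneg, cp$cpos)
      newU[[i]] <- upd$U; newV[[i]] <- upd$V
    }
    candU <- newU; candV <- newV
    new_obj <- nmfObjective(Xs, newU, newV, Ls, lambda_M, lambda_c)
    theta <- 1
    while (new_obj > obj * (1 + 1e-12) && theta > 2^-12) {
      theta <- theta / 2
      for (i in seq_len(n)) {
        newU[[i]] <- (1 - theta) * Us[[i]] + theta * candU[[i]]
        newV[[i]] <- (1 - theta) * Vs[[i]] + theta * candV[[i]]
      }
      new_obj <- nmfObjective(Xs, newU, newV, Ls, lambda_M, lambda_c)
    }
    if (new_obj > obj * (1 + 1e-12)) break
    Us <- newU; Vs <- newV
    trace <- c(trace, new_obj)
    done <- abs(obj - new_obj) < config$tol * max(obj, 1e-12)
    obj <- new_obj
    if (done) break
  }
  out <- lapply(seq_len(n), function(i) {
    nrm <- max_normalize(Vs[[i]])
    list(U = sweep(Us[[i]], 2L, nrm$scales, "*"), V = nrm$V)
  })
  attr(out, "objective") <- trace
  attr(out, "iterations") <- iter
  out
}
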