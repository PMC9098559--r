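#' Assemble the multi-scale edge-coupling feature matrix
#'
#' Concatenates the vectorized between-network edge couplings (upper
#' triangle, column-major within each scale, scales in increasing
#' order) into one subjects x features matrix: scales 2..K_max give
#' \eqn{\sum_K K(K-1)/2} features. Missing edges are imputed with the
#' column mean and flagged.
#'
#' @param coupling_sets list (per subject) of lists (per scale) of
#'   [CouplingSet-class] objects, or of K x K edge matrices.
#' @param scales integer vector of scales to include.
#' @return numeric matrix with attribute `imputed` (logical per column).
#' @export
assembleFeatureMatrix <- function(coupling_sets, scales) {
  rows <- lapply(coupling_sets, function(per_subject) {
    unlist(lapply(as.character(scales), function(key) {
      E <- per_subject[[key]]
      if (is(E, "CouplingSet")) E <- edgeMatrix(E)
      E[upper.tri(E)]
    }))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- unlist(lapply(scales, function(K) {
    pr <- which(upper.tri(diag(K)), arr.ind = TRUE)
    sprintf("s%d_e%d_%d", K, pr[, 1L], pr[, 2L])
  }))
  imputed <- rep(FALSE, ncol(X))
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) {
      fill <- if (all(bad)) 0 else mean(X[!bad, j])
      X[bad, j] <- fill
      imputed[j] <- TRUE
    }
  }
  attr(X, "imputed") <- imputed
  X
}

# Closed-form ridge path via SVD: returns coefficient matrix (p x
# n_lambda) for centered X, centered y.
ridge_path <- function(X, y, lambdas) {
  sv <- svd(X)
  d <- sv$d
  uty <- crossprod(sv$u, y)
  out <- vapply(lambdas, function(lam) {
    as.numeric(sv$v %*% (uty * d / (d^2 + lam)))
  }, numeric(ncol(X)))
  matrix(out, nrow = ncol(X))
}

#' Nested split-thirds ridge prediction
#'
#' Per repeat, subjects are randomly split into thirds: ridge
#' coefficients for every penalty in the grid are fit on the 1st third,
#' the penalty minimizing mean squared error on the 2nd third is
#' selected, and the unseen 3rd third is predicted. Covariates (age,
#' motion) are regressed out of the response using a projection fit on
#' the 1st third only, and feature standardization likewise uses 1st
#' third statistics, so the evaluation third never leaks into fitting or
#' tuning. Final per-subject predictions average over the repeats in
#' which the subject fell in the evaluation third.
#'
#' @param features subjects x features matrix.
#' @param y response (EF scores).
#' @param covariates data.frame of nuisance covariates to residualize
#'   out of y (NULL for none).
#' @param lambda_grid ridge penalties; default 20 log-spaced values
#'   spanning 1e-3 to 1e4 (features are standardized, so the grid is in
#'   units of the mean feature variance).
#' @param n_repeats number of random split repeats.
#' @param seed RNG seed.
#' @param allow_partial if TRUE, subjects that never landed in an
#'   evaluation third are dropped from the summaries instead of raising
#'   an error (used by the permutation test, where repeats are few).
#' @return list of class `pfnPrediction` with `predictions` (per
#'   subject, averaged; NA where never evaluated), `r`, `mse`,
#'   `lambda_chosen` (per repeat), `per_repeat_r`, `degenerate` flag.
#' @export
ridgeNestedPredict <- function(features, y, covariates = NULL,
                               lambda_grid = NULL, n_repeats = 100L,
                               seed = 1L, allow_partial = FALSE) {
  n <- length(y)
  stopifnot(nrow(features) == n)
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(1e-3), log(1e4), length.out = 20L))
  }
  stopifnot(length(lambda_grid) > 0, all(lambda_grid > 0))
  pred_sum <- numeric(n)
  pred_cnt <- integer(n)
  lam_chosen <- numeric(n_repeats)
  rep_r <- rep(NA_real_, n_repeats)
  rep_seeds <- derive_seeds(seed, n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    idx <- with_seed(rep_seeds[rep_i], sample.int(n))
    cut1 <- floor(n / 3); cut2 <- floor(2 * n / 3)
    third1 <- idx[seq_len(cut1)]
    third2 <- idx[(cut1 + 1L):cut2]
    third3 <- idx[(cut2 + 1L):n]

    y_work <- y
    if (!is.null(covariates)) {
      cov_df <- as.data.frame(covariates)
      rfit <- stats::lm(y ~ ., data = cbind(data.frame(y = y), cov_df),
                        subset = third1)
      y_work <- y - stats::predict(rfit, newdata = cov_df)
    }
    mu <- colMeans(features[third1, , drop = FALSE])
    sg <- apply(features[third1, , drop = FALSE], 2L, stats::sd)
    keep_sd <- sg > 0
    Xs <- sweep(features, 2L, mu)
    Xs <- sweep(Xs, 2L, ifelse(keep_sd, sg, 1), "/")
    Xs[, !keep_sd] <- 0   # uninformative in the fitting third
    y1 <- y_work[third1]
    y1c <- y1 - mean(y1)
    betas <- ridge_path(Xs[third1, , drop = FALSE], y1c, lambda_grid)
    pred2 <- Xs[third2, , drop = FALSE] %*% betas + mean(y1)
    mse2 <- colMeans((y_work[third2] - pred2)^2)
    best <- which.min(mse2)
    lam_chosen[rep_i] <- lambda_grid[best]
    p3 <- as.numeric(Xs[third3, , drop = FALSE] %*% betas[, best] + mean(y1))
    pred_sum[third3] <- pred_sum[third3] + p3
    pred_cnt[third3] <- pred_cnt[third3] + 1L
    if (stats::sd(p3) > 0) rep_r[rep_i] <- stats::cor(y[third3], p3)
  }
  covered <- pred_cnt > 0
  if (!all(covered)) {
    if (!allow_partial) {
      stop("some subjects never fell in an evaluation third; ",
           "increase n_repeats")
    }
    # summaries restricted to covered subjects (permutation-null use)
  }
  pred <- rep(NA_real_, n)
  pred[covered] <- pred_sum[covered] / pred_cnt[covered]
  # degenerate when shrinkage left every repeat with constant
  # predictions (no feature information survives)
  degenerate <- stats::sd(pred[covered]) == 0 || all(is.na(rep_r))
  r <- if (degenerate) 0 else stats::cor(y[covered], pred[covered])
  structure(list(predictions = pred, r = r,
                 mse = mean((y[covered] - pred[covered])^2),
                 lambda_chosen = lam_chosen,
                 per_repeat_r = rep_r,
                 degenerate = degenerate),
            class = "pfnPrediction")
}

#' Permutation test of the ridge prediction
#'
#' Re-runs the full nested split-thirds procedure on row-permuted EF
#' scores and compares the observed prediction correlation with the
#' null distribution; one-sided with the add-one rule.
#'
#' @param features,y,covariates,lambda_grid as [ridgeNestedPredict()].
#' @param n_repeats repeats per (observed and null) run.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param allow_partial tolerate subjects that never land in an
#'   evaluation third (their summary is computed over covered subjects);
#'   the default is lenient here because each permutation uses few
#'   repeats by design.
#' @return list with `observed_r`, `null_r`, `p_value`.
#' @export
predictionPermutationTest <- function(features, y, covariates = NULL,
                                      lambda_grid = NULL,
                                      n_repeats = 20L, n_perm = 200L,
                                      seed = 1L, allow_partial = TRUE) {
  seeds <- derive_seeds(seed, n_perm + 2L)
  obs <- ridgeNestedPredict(features, y, covariates, lambda_grid,
                            n_repeats, seed = seeds[1L],
                            allow_partial = allow_partial)
  perm_seeds <- derive_seeds(seeds[2L], n_perm)
  null_r <- vapply(seq_len(n_perm), function(b) {
    yp <- with_seed(perm_seeds[b], sample(y))
    ridgeNestedPredict(features, yp, covariates, lambda_grid,
                       n_repeats, seed = perm_seeds[b],
                       allow_partial = TRUE)$r
  }, numeric(1))
  p <- (1 + sum(null_r >= obs$r)) / (n_perm + 1)
  list(observed_r = obs$r, null_r = null_r, p_value = p)
}
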