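#' Generalized estimating equations across scales
#'
#' Gaussian GEE with an exchangeable working correlation and robust
#' (sandwich) covariance, used to test scale effects on coupling while
#' accounting for the covariance between same-subject measurements
#' across scales. Smooth terms are pre-expanded into fixed spline basis
#' columns (mgcv bases with fixed, unpenalized degrees of freedom), and
#' the tested block — the scale smooth, or a scale-by-age /
#' scale-by-EF product-basis block — is assessed with a joint Wald
#' chi-square on the robust covariance.
#'
#' Estimation iterates: (1) update the exchangeable correlation
#' parameter from Pearson residual cross-products, (2) update the
#' coefficients by the working-correlation-weighted normal equations.
#' Clusters with a single observation reduce the fit to robust OLS (with
#' a warning).
#'
#' @param data long-format data.frame (one row per subject x scale).
#' @param yvar response column name.
#' @param cluster subject id column name.
#' @param smooth_vars columns expanded into fixed spline bases.
#' @param linear_vars columns entering linearly.
#' @param interaction optional character length-2: a product-basis
#'   (tensor-type) interaction block of the two named smooth columns.
#' @param tested which block the Wald test targets: a smooth variable
#'   name or `"interaction"`.
#' @param k basis dimension per smooth (fixed, unpenalized).
#' @return list of class `pfnGee` with `coefficients`, `alpha`
#'   (exchangeable correlation), `vbeta` (sandwich), `wald`, `df`,
#'   `p_value`, `tested_idx`, `design`.
#' @export
fitGee <- function(data, yvar, cluster, smooth_vars = character(),
                   linear_vars = character(), interaction = NULL,
                   tested = smooth_vars[1L], k = 4L) {
  y <- data[[yvar]]
  id <- as.factor(data[[cluster]])
  X <- matrix(1, nrow(data), 1L)
  colnames(X) <- "(Intercept)"
  block_idx <- list()
  basis_fns <- list()
  for (v in smooth_vars) {
    sc <- mgcv::smoothCon(mgcv::s(get("x"), k = k, fx = TRUE),
                          data = data.frame(x = data[[v]]),
                          absorb.cons = TRUE)[[1L]]
    B <- sc$X
    colnames(B) <- sprintf("s(%s).%d", v, seq_len(ncol(B)))
    block_idx[[v]] <- ncol(X) + seq_len(ncol(B))
    basis_fns[[v]] <- sc
    X <- cbind(X, B)
  }
  for (v in linear_vars) {
    block_idx[[v]] <- ncol(X) + 1L
    X <- cbind(X, stats::setNames(data.frame(data[[v]]), v)[[1L]])
    colnames(X)[ncol(X)] <- v
  }
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2L,
              all(interaction %in% names(basis_fns)))
    B1 <- X[, block_idx[[interaction[1L]]], drop = FALSE]
    B2 <- X[, block_idx[[interaction[2L]]], drop = FALSE]
    prod_cols <- do.call(cbind, lapply(seq_len(ncol(B1)), function(i) {
      B1[, i] * B2
    }))
    colnames(prod_cols) <- sprintf("ti.%d", seq_len(ncol(prod_cols)))
    block_idx[["interaction"]] <- ncol(X) + seq_len(ncol(prod_cols))
    X <- cbind(X, prod_cols)
  }

  cl <- split(seq_len(nrow(X)), id)
  sizes <- lengths(cl)
  if (all(sizes == 1L)) {
    warning("one observation per cluster: fitting robust OLS")
  }
  p <- ncol(X)
  beta <- stats::coef(stats::lm.fit(X, y))
  beta[is.na(beta)] <- 0
  alpha <- 0
  for (it in seq_len(25L)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (length(y) - p)
    num <- 0; den <- 0
    for (rows in cl) {
      ni <- length(rows)
      if (ni < 2L) next
      ei <- e[rows] / sqrt(phi)
      num <- num + (sum(ei)^2 - sum(ei^2)) / 2
      den <- den + ni * (ni - 1) / 2
    }
    alpha_new <- if (den > 0) num / den else 0
    alpha_new <- max(min(alpha_new, 0.99), -0.99)
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (rows in cl) {
      ni <- length(rows)
      Ri_inv <- exchangeable_inverse(ni, alpha_new)
      Xi <- X[rows, , drop = FALSE]
      XtR <- crossprod(Xi, Ri_inv)
      A <- A + XtR %*% Xi
      b <- b + XtR %*% y[rows]
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- as.numeric(beta_new)
    conv <- delta < 1e-8 && abs(alpha_new - alpha) < 1e-8
    alpha <- alpha_new
    if (conv) break
  }
  # sandwich covariance
  e <- y - X %*% beta
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (rows in cl) {
    ni <- length(rows)
    Ri_inv <- exchangeable_inverse(ni, alpha)
    Xi <- X[rows, , drop = FALSE]
    XtR <- crossprod(Xi, Ri_inv)
    A <- A + XtR %*% Xi
    u <- XtR %*% e[rows]
    M <- M + u %*% t(u)
  }
  Ainv <- solve(A)
  vbeta <- Ainv %*% M %*% Ainv
  idx <- block_idx[[tested]]
  bb <- beta[idx]
  W <- as.numeric(t(bb) %*% solve(vbeta[idx, idx, drop = FALSE], bb))
  pval <- stats::pchisq(W, df = length(idx), lower.tail = FALSE)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 alpha = alpha, vbeta = vbeta, wald = W,
                 df = length(idx), p_value = pval,
                 tested_idx = idx, design = X),
            class = "pfnGee")
}

# Inverse of the ni x ni exchangeable correlation matrix
# (1-a) I + a J, in closed form.
exchangeable_inverse <- function(ni, a) {
  if (ni == 1L) return(matrix(1, 1L, 1L))
  c1 <- 1 / (1 - a)
  c2 <- -a / ((1 - a) * (1 + (ni - 1) * a))
  M <- matrix(c2, ni, ni)
  diag(M) <- c1 + c2
  M
}
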