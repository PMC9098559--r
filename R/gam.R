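#' Penalized-spline regression fit
#'
#' Fits a generalized additive model with thin-plate penalized splines
#' for the requested smooth terms and unpenalized parametric covariates,
#' with the smoothing parameter chosen by restricted maximum likelihood
#' (REML). This is the workhorse behind the per-unit age and EF models,
#' e.g. `coupling ~ s(age) + sex + motion`.
#'
#' @param y response vector.
#' @param data data.frame holding the covariates.
#' @param smooth_terms character vector of columns modelled as penalized
#'   smooths.
#' @param linear_terms character vector of columns entering linearly.
#' @param k basis dimension per smooth (mgcv default when NULL).
#' @param sp optional fixed smoothing parameter(s), bypassing REML.
#' @return list of class `pfnGam` with the mgcv fit (`model`), the
#'   adjusted R-squared (`adj_r2`), per-smooth effective degrees of
#'   freedom (`edf`) and the pieces needed downstream.
#' @export
fitGamSmooth <- function(y, data, smooth_terms, linear_terms = character(),
                         k = NULL, sp = NULL) {
  stopifnot(all(c(smooth_terms, linear_terms) %in% names(data)))
  df <- data.frame(.y = y, data[, c(smooth_terms, linear_terms),
                                drop = FALSE])
  lin_ok <- linear_terms[vapply(linear_terms, function(v) {
    length(unique(df[[v]])) > 1L
  }, logical(1))]
  dropped <- setdiff(linear_terms, lin_ok)
  if (length(dropped)) {
    stop("rank-deficient design: constant columns ",
         paste(dropped, collapse = ", "))
  }
  sm <- if (is.null(k)) {
    sprintf("s(%s)", smooth_terms)
  } else {
    sprintf("s(%s, k = %d)", smooth_terms, k)
  }
  rhs <- paste(c(sm, lin_ok), collapse = " + ")
  if (rhs == "") rhs <- "1"
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- mgcv::gam(form, data = df, method = "REML", sp = sp)
  structure(list(model = fit,
                 adj_r2 = summary(fit)$r.sq,
                 edf = summary(fit)$edf,
                 smooth_terms = smooth_terms,
                 linear_terms = lin_ok,
                 data = df),
            class = "pfnGam")
}

#' Signed effect size and significance of a model term
#'
#' Effect size is the change in adjusted R-squared between the full and
#' the nested (reduced) fit, signed by the coefficient of the term of
#' interest in an equivalent linear model; significance comes from an
#' ANOVA (F) comparison of the two fits.
#'
#' @param full,reduced `pfnGam` fits on the same data, the reduced model
#'   omitting the term of interest.
#' @param sign_term column name whose linear coefficient supplies the
#'   sign; NULL leaves the effect unsigned (positive).
#' @return list with `delta_r2_adj`, `p_value`, `sign`.
#' @export
gamEffect <- function(full, reduced, sign_term = NULL) {
  delta <- full$adj_r2 - reduced$adj_r2
  an <- stats::anova(reduced$model, full$model, test = "F")
  p <- an[2L, "Pr(>F)"]
  if (is.na(p)) p <- 1
  sgn <- 1
  if (!is.null(sign_term)) {
    lin_terms <- unique(c(full$smooth_terms, full$linear_terms))
    lform <- stats::as.formula(paste(".y ~", paste(lin_terms, collapse = " + ")))
    lfit <- stats::lm(lform, data = full$data)
    sgn <- sign(stats::coef(lfit)[[sign_term]])
    if (sgn == 0) sgn <- 1
  }
  list(delta_r2_adj = sgn * delta, p_value = p, sign = sgn)
}

#' Windows of credible change in a fitted smooth
#'
#' Finite-difference first derivative of one fitted smooth on a grid,
#' with pointwise confidence bands from simulating coefficients out of
#' the fit's posterior; returns the contiguous grid runs where the band
#' excludes zero, i.e. the windows of credible increase or decrease.
#'
#' @param fit a `pfnGam` fit.
#' @param term the smooth covariate name.
#' @param grid evaluation points (default: 200 points spanning the
#'   observed range).
#' @param level confidence level (default 0.95, pointwise).
#' @param n_sim posterior coefficient draws.
#' @param seed RNG seed for the draws.
#' @return data.frame with columns start, end, sign (one row per
#'   window); zero rows when the band never excludes 0.
#' @export
derivativeWindows <- function(fit, term, grid = NULL, level = 0.95,
                              n_sim = 1000L, seed = 1L) {
  model <- fit$model
  xvals <- fit$data[[term]]
  if (is.null(grid)) {
    grid <- seq(min(xvals), max(xvals), length.out = 200L)
  }
  eps <- diff(range(xvals)) / 1e4
  nd_hi <- nd_lo <- fit$data[rep(1L, length(grid)), , drop = FALSE]
  nd_hi[[term]] <- grid + eps
  nd_lo[[term]] <- grid - eps
  Xp <- (stats::predict(model, newdata = nd_hi, type = "lpmatrix") -
         stats::predict(model, newdata = nd_lo, type = "lpmatrix")) / (2 * eps)
  # only the columns of this term's smooth vary; others cancel in the difference
  beta <- stats::coef(model)
  Vp <- stats::vcov(model)
  sims <- with_seed(seed, {
    ch <- chol(Vp + diag(1e-12, ncol(Vp)))
    matrix(stats::rnorm(n_sim * length(beta)), n_sim) %*% ch
  })
  sims <- sweep(sims, 2L, beta, "+")
  deriv_draws <- sims %*% t(Xp)               # n_sim x n_grid
  alpha <- (1 - level) / 2
  lo <- apply(deriv_draws, 2L, stats::quantile, probs = alpha)
  hi <- apply(deriv_draws, 2L, stats::quantile, probs = 1 - alpha)
  sig <- ifelse(lo > 0, 1L, ifelse(hi < 0, -1L, 0L))
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- runs$values != 0L
  data.frame(start = grid[starts[keep]], end = grid[ends[keep]],
             sign = runs$values[keep])
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false discovery rate control: flags the p-values rejected at
#' level q.
#'
#' @param p_values numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return logical vector of rejections.
#' @export
fdrBh <- function(p_values, q = 0.05) {
  stats::p.adjust(p_values, method = "BH") <= q
}
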