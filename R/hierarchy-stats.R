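#' Regression of effect sizes on network hierarchy position
#'
#' Ordinary least squares of per-network effect sizes on the networks'
#' hierarchy values, optionally with a squared term (the quadratic model
#' used for EF effects, where associations concentrate at both hierarchy
#' extremes). Confidence intervals come from resampling the
#' network-scale units with replacement; a Spearman correlation is
#' reported alongside as the second-order effect size.
#'
#' @param effects per-unit effect sizes (e.g. signed delta adjusted R2).
#' @param h_values matching hierarchy values.
#' @param quadratic include the squared hierarchy term.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param level CI level.
#' @return list with `coefficients`, `ci` (percentile bootstrap),
#'   `spearman`, and the `lm` fit.
#' @export
hierarchyRegression <- function(effects, h_values, quadratic = FALSE,
                                n_boot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(length(effects) == length(h_values))
  df <- data.frame(e = effects, h = h_values, h2 = h_values^2)
  form <- if (quadratic) e ~ h + h2 else e ~ h
  fit <- stats::lm(form, data = df)
  n <- nrow(df)
  boot <- with_seed(seed, {
    t(replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      stats::coef(stats::lm(form, data = df[idx, ]))
    }))
  })
  alpha <- (1 - level) / 2
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  list(coefficients = stats::coef(fit), ci = ci,
       spearman = suppressWarnings(
         stats::cor(effects, h_values, method = "spearman")),
       fit = fit)
}

#' Regression of edge effects on hierarchical distance
#'
#' Slope of edge-level effect sizes on the hierarchical distance of each
#' edge, with a unit-resampling bootstrap CI, plus the partial
#' correlation of effects with hierarchical distance controlling for the
#' mean Euclidean distance between the networks (the geometric
#' sensitivity covariate).
#'
#' @param edge_effects per-edge effect sizes.
#' @param h_dist per-edge hierarchical distances.
#' @param euclid_dist per-edge mean Euclidean distances (NULL skips the
#'   partial correlation).
#' @param n_boot,seed,level bootstrap settings.
#' @return list with `slope`, `ci`, `pearson`, `partial_r`.
#' @export
distanceRegression <- function(edge_effects, h_dist, euclid_dist = NULL,
                               n_boot = 1000L, seed = 1L, level = 0.95) {
  df <- data.frame(e = edge_effects, d = h_dist)
  fit <- stats::lm(e ~ d, data = df)
  n <- nrow(df)
  boot <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      stats::coef(stats::lm(e ~ d, data = df[idx, ]))[2L]
    })
  })
  alpha <- (1 - level) / 2
  partial_r <- NA_real_
  if (!is.null(euclid_dist)) {
    re <- stats::resid(stats::lm(edge_effects ~ euclid_dist))
    rd <- stats::resid(stats::lm(h_dist ~ euclid_dist))
    partial_r <- stats::cor(re, rd)
  }
  list(slope = stats::coef(fit)[[2L]],
       ci = stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE),
       pearson = stats::cor(edge_effects, h_dist),
       partial_r = partial_r)
}

#' Bivariate smooth of edge effects over both networks' hierarchy
#'
#' Fits a tensor-product smooth of edge-level effects over the hierarchy
#' positions of the two networks forming each edge (for visualization of
#' how developmental effects vary jointly along the hierarchy), with
#' inference on a simplified linear interaction model via the same
#' unit-resampling bootstrap.
#'
#' @param edge_effects per-edge effect sizes.
#' @param h_A,h_B hierarchy values of the two networks per edge.
#' @param n_boot,seed,level bootstrap settings.
#' @return list with the mgcv `surface` fit, `interaction` coefficient
#'   of the linear h_A:h_B term, and its bootstrap `ci`.
#' @export
tensorSurface <- function(edge_effects, h_A, h_B, n_boot = 1000L,
                          seed = 1L, level = 0.95) {
  df <- data.frame(e = edge_effects, hA = h_A, hB = h_B)
  kt <- max(3L, min(5L, floor(sqrt(nrow(df)) / 2)))
  surface <- mgcv::gam(e ~ te(hA, hB, k = kt), data = df, method = "REML")
  lfit <- stats::lm(e ~ hA * hB, data = df)
  n <- nrow(df)
  boot <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      stats::coef(stats::lm(e ~ hA * hB, data = df[idx, ]))[["hA:hB"]]
    })
  })
  alpha <- (1 - level) / 2
  list(surface = surface,
       interaction = stats::coef(lfit)[["hA:hB"]],
       ci = stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Second-order trend of a per-scale statistic
#'
#' Pearson correlation between scale and a per-scale statistic (e.g. the
#' MAD-hierarchy spatial correlation at each scale), with a bootstrap CI
#' obtained by recomputing the per-scale statistic on resampled subjects
#' via a user hook. A zero-variance statistic yields correlation 0 with
#' a flag.
#'
#' @param per_scale_stats numeric vector, one value per scale.
#' @param scales the scale values (default: their index).
#' @param recompute optional function(subject_indices) returning the
#'   per-scale statistic vector for a bootstrap resample of subjects.
#' @param n_subjects number of subjects to resample from (required with
#'   `recompute`).
#' @param n_boot,seed,level bootstrap settings.
#' @return list with `correlation`, `ci` (NULL without `recompute`),
#'   `degenerate` flag.
#' @export
scaleTrend <- function(per_scale_stats, scales = seq_along(per_scale_stats),
                       recompute = NULL, n_subjects = NULL,
                       n_boot = 1000L, seed = 1L, level = 0.95) {
  degenerate <- stats::sd(per_scale_stats) == 0 || stats::sd(scales) == 0
  r <- if (degenerate) 0 else stats::cor(scales, per_scale_stats)
  ci <- NULL
  if (!is.null(recompute)) {
    stopifnot(!is.null(n_subjects))
    boot <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(n_subjects, n_subjects, replace = TRUE)
        st <- recompute(idx)
        if (stats::sd(st) == 0) 0 else stats::cor(scales, st)
      })
    })
    alpha <- (1 - level) / 2
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)
  }
  list(correlation = r, ci = ci, degenerate = degenerate)
}
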