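#' Default pipeline configuration
#'
#' Desk-scale settings for the full synthetic pipeline. The `paper`
#' profile raises the resampling counts to the study-scale conventions
#' (100-subject bootstrap subsets, 50 atlas replicates, 1000 bootstrap
#' and permutation resamples); the `desk` profile keeps every stage
#' runnable on a single CPU in minutes.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... named overrides of any entry (nested lists are replaced
#'   wholesale).
#' @return a named configuration list.
#' @export
pipelineConfig <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = 1L,
    out_dir = NULL,
    synthetic = list(),           # overrides for syntheticConfig()
    scales = c(2L, 4L, 7L),
    nmf = list(alpha = 1, beta = 10, max_iter = 150L, tol = 1e-6),
    atlas = list(n_subset = 20L, n_reps = 10L),
    stats = list(n_boot = 200L, gam_k = 4L),
    predict = list(n_repeats = 20L, n_perm = 100L)
  )
  if (profile == "paper") {
    cfg$atlas <- list(n_subset = 100L, n_reps = 50L)
    cfg$stats <- list(n_boot = 1000L, gam_k = 10L)
    cfg$predict <- list(n_repeats = 100L, n_perm = 1000L)
    cfg$scales <- 2:30
    cfg$nmf$max_iter <- 300L
  }
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema check: scale range and counts must be admissible. Errors list
#' every offending key.
#'
#' @param cfg configuration list (or path to a YAML file holding one).
#' @return the validated configuration, invisibly.
#' @export
validateConfig <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  bad <- character()
  if (is.character(cfg$scales)) {
    parts <- as.integer(strsplit(cfg$scales, ":")[[1L]])
    if (length(parts) == 2L && parts[1L] <= parts[2L]) {
      cfg$scales <- parts[1L]:parts[2L]
    } else {
      bad <- c(bad, "scales")
    }
  }
  if (!length(bad) && (any(cfg$scales < 2) || is.unsorted(cfg$scales))) {
    bad <- c(bad, "scales")
  }
  if (!is.null(cfg$synthetic$n_subjects) && cfg$synthetic$n_subjects < 4) {
    bad <- c(bad, "synthetic.n_subjects")
  }
  if (cfg$atlas$n_reps < 2) bad <- c(bad, "atlas.n_reps")
  if (cfg$nmf$alpha < 0 || cfg$nmf$beta < 0) bad <- c(bad, "nmf.alpha/beta")
  if (cfg$stats$n_boot < 1) bad <- c(bad, "stats.n_boot")
  if (length(bad)) {
    stop("invalid configuration keys: ", paste(unique(bad), collapse = ", "))
  }
  invisible(cfg)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate, preprocess, atlas construction, network
#' personalization, coupling quantification, hierarchy-aligned
#' statistics, and EF prediction, writing stage outputs as plain-text
#' tables under `out_dir` together with a YAML run manifest (config
#' snapshot, seeds, per-stage wall time, output digests). A rerun with
#' an unchanged configuration skips stages whose outputs already exist
#' with matching digests.
#'
#' @param cfg from [pipelineConfig()] (or a YAML path).
#' @param out_dir output directory (overrides `cfg$out_dir`).
#' @return the run manifest, invisibly; its `results` entry carries the
#'   headline statistics (hierarchy slope, distance slope, EF quadratic
#'   term, prediction r and permutation p).
#' @export
runPipeline <- function(cfg = pipelineConfig(), out_dir = cfg$out_dir) {
  cfg <- validateConfig(cfg)
  if (is.null(out_dir)) stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$out_dir <- out_dir
  cfg_digest <- digest_config(cfg)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  prev <- if (file.exists(manifest_path)) {
    yaml::read_yaml(manifest_path)
  } else NULL
  reuse <- !is.null(prev) && identical(prev$config_digest, cfg_digest) &&
    all(file.exists(file.path(out_dir, names(prev$digests)))) &&
    identical(unname(tools::md5sum(file.path(out_dir, names(prev$digests)))),
              unname(unlist(prev$digests)))
  manifest <- list(config_digest = cfg_digest, config = cfg,
                   timing = list(), stages = character())
  t_all <- proc.time()[3L]

  scfg <- do.call(syntheticConfig,
                  c(cfg$synthetic,
                    list(scales = cfg$scales, seed = cfg$seed)))
  study <- simulateStudy(scfg)
  n <- nrow(study$cohort)
  manifest$timing$simulate <- proc.time()[3L] - t_all
  writeCohort(study$cohort, file.path(out_dir, "cohort.tsv"))
  writeMeshOFF(study$mesh, file.path(out_dir, "mesh.off"))
  utils::write.table(data.frame(vertex = seq_along(study$hierarchy),
                                hierarchy = study$hierarchy),
                     file.path(out_dir, "hierarchy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (reuse) {
    manifest <- prev
    manifest$stages <- c(manifest$stages, "all-skipped")
    manifest$skipped <- TRUE
    yaml::write_yaml(manifest_drop_big(manifest), manifest_path)
    return(invisible(manifest))
  }

  # preprocess + subject affinity graphs
  t0 <- proc.time()[3L]
  Xp <- lapply(study$timeseries, preprocessForNmf)
  Ls <- lapply(Xp, function(X) buildAffinity(study$mesh, X)$L)
  L_group <- buildAffinity(study$mesh, do.call(rbind, Xp))$L
  manifest$timing$preprocess <- proc.time()[3L] - t0

  # atlases + personalization + coupling per scale
  seeds <- derive_seeds(cfg$seed + 1L, length(cfg$scales) * 2L + 2L)
  subjV <- list(); couplings <- list(); atlases <- list()
  t0 <- proc.time()[3L]
  for (si in seq_along(cfg$scales)) {
    K <- cfg$scales[si]
    ncfg <- nmfConfig(K, alpha = cfg$nmf$alpha, beta = cfg$nmf$beta,
                      max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol,
                      seed = seeds[si])
    reps <- bootstrapGroupAtlases(Xp, L_group, ncfg,
                                  n_subset = min(cfg$atlas$n_subset, n),
                                  n_reps = cfg$atlas$n_reps,
                                  seed = seeds[si])
    atlas <- fuseAtlases(reps, K, seed = seeds[length(cfg$scales) + si])
    atlases[[as.character(K)]] <- atlas
    writeLoadings(atlasLoadings(atlas),
                  file.path(out_dir, sprintf("atlas_K%d.tsv", K)))
    subjV[[as.character(K)]] <- lapply(seq_len(n), function(i) {
      personalizeNetworks(Xp[[i]], Ls[[i]], atlas, ncfg)
    })
    couplings[[as.character(K)]] <- lapply(seq_len(n), function(i) {
      computeCoupling(scale(study$timeseries[[i]]),
                      hardPartition(subjV[[as.character(K)]][[i]]), K,
                      subject_id = study$cohort$subject_id[i])
    })
  }
  manifest$timing$networks <- proc.time()[3L] - t0

  # variability + hierarchy statistics
  t0 <- proc.time()[3L]
  results <- list()
  mad_r <- vapply(as.character(cfg$scales), function(key) {
    m <- madMap(subjV[[key]])$mad
    stats::cor(m, study$hierarchy)
  }, numeric(1))
  results$mad_hierarchy_r <- mad_r
  results$mad_scale_trend <- scaleTrend(mad_r, cfg$scales)$correlation

  eff_net <- list(); eff_edge <- list()
  for (key in as.character(cfg$scales)) {
    K <- as.integer(key)
    gpart <- hardPartition(atlasLoadings(atlases[[key]]))
    hv <- networkHierarchyValues(gpart, study$hierarchy)
    ed <- euclideanEdgeDistance(study$mesh, gpart)
    cov_df <- study$cohort
    for (k in seq_len(K)) {
      yk <- vapply(couplings[[key]], function(cs) networkCouplingOf(cs)[k],
                   numeric(1))
      if (all(is.na(yk))) next
      full <- fitGamSmooth(yk, cov_df, "age", c("sex", "motion"),
                           k = cfg$stats$gam_k)
      red <- fitGamSmooth(yk, cov_df, character(), c("sex", "motion"))
      ef <- gamEffect(full, red, sign_term = "age")
      eff_net[[length(eff_net) + 1L]] <- data.frame(
        scale = K, network = k, h = hv$network[k],
        delta = ef$delta_r2_adj, p = ef$p_value)
    }
    prs <- which(upper.tri(diag(K)), arr.ind = TRUE)
    for (e in seq_len(nrow(prs))) {
      A <- prs[e, 1L]; B <- prs[e, 2L]
      ye <- vapply(couplings[[key]], function(cs) edgeMatrix(cs)[A, B],
                   numeric(1))
      if (all(is.na(ye))) next
      ok <- is.finite(ye)
      full <- fitGamSmooth(ye[ok], cov_df[ok, ], "age", c("sex", "motion"),
                           k = cfg$stats$gam_k)
      red <- fitGamSmooth(ye[ok], cov_df[ok, ], character(),
                          c("sex", "motion"))
      ef <- gamEffect(full, red, sign_term = "age")
      eff_edge[[length(eff_edge) + 1L]] <- data.frame(
        scale = K, netA = A, netB = B,
        hdist = hv$edge_distance[A, B], euclid = ed[A, B],
        hA = hv$network[A], hB = hv$network[B],
        delta = ef$delta_r2_adj, p = ef$p_value)
    }
  }
  eff_net <- do.call(rbind, eff_net)
  eff_edge <- do.call(rbind, eff_edge)
  eff_net$fdr <- fdrBh(eff_net$p)
  eff_edge$fdr <- fdrBh(eff_edge$p)
  utils::write.table(eff_net, file.path(out_dir, "age_effects_network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eff_edge, file.path(out_dir, "age_effects_edge.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hr <- hierarchyRegression(eff_net$delta, eff_net$h,
                            n_boot = cfg$stats$n_boot, seed = cfg$seed)
  dr <- distanceRegression(eff_edge$delta, eff_edge$hdist, eff_edge$euclid,
                           n_boot = cfg$stats$n_boot, seed = cfg$seed)
  results$hierarchy_slope <- unname(hr$coefficients[2L])
  results$hierarchy_spearman <- hr$spearman
  results$hdist_slope <- dr$slope
  results$hdist_partial_r <- dr$partial_r
  manifest$timing$stats <- proc.time()[3L] - t0

  # prediction
  t0 <- proc.time()[3L]
  per_subject <- lapply(seq_len(n), function(i) {
    out <- lapply(as.character(cfg$scales), function(key) {
      couplings[[key]][[i]]
    })
    names(out) <- as.character(cfg$scales)
    out
  })
  feats <- assembleFeatureMatrix(per_subject, cfg$scales)
  pred <- ridgeNestedPredict(feats, study$cohort$ef,
                             covariates = study$cohort[, c("age", "motion")],
                             n_repeats = cfg$predict$n_repeats,
                             seed = cfg$seed)
  results$prediction_r <- pred$r
  results$prediction_mse <- pred$mse
  if (cfg$predict$n_perm > 0) {
    pt <- predictionPermutationTest(
      feats, study$cohort$ef,
      covariates = study$cohort[, c("age", "motion")],
      n_repeats = max(2L, ceiling(cfg$predict$n_repeats / 4)),
      n_perm = cfg$predict$n_perm, seed = cfg$seed)
    results$prediction_p <- pt$p_value
  }
  utils::write.table(
    data.frame(subject_id = study$cohort$subject_id,
               ef = study$cohort$ef, predicted = pred$predictions),
    file.path(out_dir, "ef_predictions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$timing$predict <- proc.time()[3L] - t0

  res_df <- data.frame(statistic = names(unlist(results)),
                       value = unlist(results))
  utils::write.table(res_df, file.path(out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, pattern = "\\.(tsv|off)$")
  manifest$digests <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$digests) <- outputs
  manifest$results <- results
  manifest$stages <- c("simulate", "preprocess", "atlas", "personalize",
                       "coupling", "stats", "predict")
  manifest$timing$total <- proc.time()[3L] - t_all
  yaml::write_yaml(manifest_drop_big(manifest), manifest_path)
  invisible(manifest)
}

digest_config <- function(cfg) {
  cfg$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

# manifest copy safe for YAML serialization
manifest_drop_big <- function(m) {
  m$config$out_dir <- NULL
  m$results <- lapply(m$results, function(x) {
    if (is.numeric(x)) as.numeric(x) else x
  })
  m
}
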