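#' Default configuration of the synthetic study
#'
#' Bundles the generator settings that emulate the structure of a
#' developmental surface-fMRI cohort: a spherical cortical mesh, nested
#' multi-scale spatially contiguous networks, a smooth
#' unimodal-to-transmodal hierarchy map, subject-specific topographic
#' perturbation growing along the hierarchy, between-network coupling
#' with planted hierarchy-distance and age effects, and an executive
#' function score built from selected couplings. Defaults are desk-scale:
#' 162 vertices, 40 subjects, 555 timepoints, scales 2/4/7 with BOLD
#' courses generated at scale 4.
#'
#' @param ... named overrides of any default entry.
#' @return a named list of generator settings.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    subdivisions = 2L,        # icosphere: 162 vertices
    n_subjects = 40L,
    n_timepoints = 555L,      # matches the concatenated acquisition length
    age_range = c(8, 23),
    scales = c(2L, 4L, 7L),
    gen_scale = 4L,           # scale whose planted networks drive the BOLD courses
    hierarchy_noise = 0.3,
    hierarchy_smooth = 10L,
    topo_sd = 0.5,            # topographic perturbation scale (x hierarchy value)
    kernel_sharpness = 0.8,   # loading-kernel bandwidth factor (see vignette)
    noise_sd = 0.05,          # vertex measurement noise (course sd units)
    course_shift = 3,         # additive course offset, keeps signals BOLD-positive
    rho0 = 0.35,              # edge coupling at zero hierarchical distance
    hdist_slope = 0.45,       # coupling loss per unit normalized hierarchical distance
    age_slope = 0.02,         # per-year coupling change scale
    age0 = 15.5,              # age at which coupling equals the cross-sectional model
    subject_dev_sd = 0.08,    # stable per-subject edge deviations
    ef_signal_sd = 1.2,       # sd of the coupling-driven EF component (z units)
    ef_age_slope = 0.1,       # EF maturation per year (z units)
    ef_noise_sd = 0.4,
    seed = 1L
  )
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  cfg
}

#' Synthetic functional hierarchy map
#'
#' A smooth per-vertex scalar emulating a principal functional gradient:
#' the vertex z-coordinate (one pole unimodal, the other transmodal) plus
#' spatially smoothed Gaussian noise, rescaled to \[0, 1\]. Higher values
#' are more transmodal.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param seed integer RNG seed.
#' @param noise_sd sd of the smoothed noise component relative to the
#'   unit-scaled z gradient; 0 gives the pure rescaled z-coordinate.
#' @param smooth_iters neighbourhood-averaging passes applied to the noise.
#' @return numeric vector of length `nVertices(mesh)` in \[0, 1\].
#' @export
makeHierarchyMap <- function(mesh, seed = 1L, noise_sd = 0.3,
                             smooth_iters = 10L) {
  z <- vertexCoords(mesh)[, 3L]
  h <- z
  if (noise_sd > 0) {
    eps <- with_seed(seed, stats::rnorm(nVertices(mesh)))
    eps <- smooth_on_mesh(eps, neighborLists(mesh), smooth_iters)
    eps <- as.numeric(scale(eps))
    h <- z + noise_sd * eps
  }
  (h - min(h)) / (max(h) - min(h))
}

# Repeated local averaging over mesh neighbours (value + neighbours mean).
smooth_on_mesh <- function(values, neighbors, iters) {
  for (i in seq_len(iters)) {
    values <- vapply(seq_along(values), function(v) {
      mean(values[c(v, neighbors[[v]])])
    }, numeric(1))
  }
  values
}

# Deterministic recursive bipartition of the mesh: always split the
# largest current cluster at its two mutually farthest member vertices,
# members going to the nearest of the two split seeds. Returns the K seed
# vertices; the sequence is nested across K for a fixed mesh and seed.
split_seeds <- function(mesh, K, seed) {
  co <- vertexCoords(mesh)
  S <- nrow(co)
  # first split: extremes along a seeded random direction (the sphere is
  # symmetric, so a direction is needed to break ties deterministically)
  u <- with_seed(seed, stats::rnorm(3))
  u <- u / sqrt(sum(u^2))
  proj <- as.numeric(co %*% u)
  members <- list(seq_len(S))
  cseeds <- NA_integer_
  first <- TRUE
  while (length(members) < K) {
    tgt <- which.max(lengths(members))
    idx <- members[[tgt]]
    if (first) {
      s1 <- idx[which.max(proj[idx])]
      s2 <- idx[which.min(proj[idx])]
      first <- FALSE
    } else {
      dd <- as.matrix(stats::dist(co[idx, , drop = FALSE]))
      far <- arrayInd(which.max(dd), dim(dd))
      s1 <- idx[min(far[1L], far[2L])]
      s2 <- idx[max(far[1L], far[2L])]
    }
    # alternate assignment and medoid recentering inside the parent so
    # both child cells stay compact and inside the parent region
    for (lloyd in seq_len(4L)) {
      d1 <- rowSums(sweep(co[idx, , drop = FALSE], 2L, co[s1, ])^2)
      d2 <- rowSums(sweep(co[idx, , drop = FALSE], 2L, co[s2, ])^2)
      m1 <- idx[d1 <= d2]; m2 <- idx[d1 > d2]
      s1 <- medoid(co, m1); s2 <- medoid(co, m2)
    }
    members[[tgt]] <- m1
    cseeds[tgt] <- s1
    members[[length(members) + 1L]] <- m2
    cseeds[length(members)] <- s2
  }
  labels <- integer(S)
  for (k in seq_along(members)) labels[members[[k]]] <- k
  list(seeds = cseeds, labels = labels)
}

# member vertex minimizing the summed squared distance to its co-members
medoid <- function(co, members) {
  if (length(members) == 1L) return(members)
  sub <- co[members, , drop = FALSE]
  ctr <- colMeans(sub)
  members[which.min(rowSums(sweep(sub, 2L, ctr)^2))]
}

#' Planted multi-scale group networks
#'
#' Builds K spatially contiguous soft networks by recursive bipartition
#' of the mesh (always splitting the largest cluster), so that for a
#' fixed seed the network centres at scale K are nested refinements of
#' the K = 2 bipartition: each finer network lies predominantly inside
#' one of the two coarse halves. Loadings are Gaussian distance-kernel
#' weights around each network centre with a common bandwidth, then
#' max-normalized per network, so each vertex's argmax label equals its
#' nearest-centre partition.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param K number of networks, K >= 2.
#' @param seed integer seed controlling the (otherwise tie-ridden) first
#'   split direction; use one seed across scales to obtain nesting.
#' @param sharpness kernel bandwidth factor; smaller values shrink the
#'   plateau, giving peakier loadings with smaller off-network tails.
#' @return S x K nonnegative loading matrix, column max 1, with the
#'   centre vertex indices in `attr(, "seeds")`.
#' @export
makeGroupNetworks <- function(mesh, K, seed = 1L, sharpness = 0.8) {
  stopifnot(K >= 2)
  co <- vertexCoords(mesh)
  tree <- split_seeds(mesh, as.integer(K), seed)
  seeds <- tree$seeds
  lab <- tree$labels
  D2 <- vapply(seeds, function(s) {
    rowSums(sweep(co, 2L, co[s, ])^2)
  }, numeric(nrow(co)))
  # common kernel bandwidth: rms member-to-centre distance, averaged
  r2 <- mean(vapply(seq_len(K), function(k) {
    mean(D2[lab == k, k])
  }, numeric(1)))
  # mildly plateau-shaped kernel: flat enough over the member region to
  # match what range-normalized data can identify, falling off fast at
  # the parcel border so off-network tails stay small
  V <- exp(-(D2 / (2 * r2 * sharpness))^1.5)
  # the recursive-split membership is the planted partition: where the
  # plain kernel argmax disagrees (cell borders), lift the member loading
  # just above the competing one so argmax reproduces the nested labels
  rowmax <- apply(V, 1L, max)
  mism <- which(max.col(V, ties.method = "first") != lab)
  if (length(mism)) {
    V[cbind(mism, lab[mism])] <- rowmax[mism] * 1.02
  }
  V <- max_normalize(V)$V
  attr(V, "seeds") <- seeds
  V
}

#' Subject-specific topographic perturbation of group networks
#'
#' Applies a per-vertex, per-network multiplicative perturbation
#' \eqn{V_{sk}(1+\epsilon_{sk})}, \eqn{\epsilon_{sk} \sim N(0, (sd
#' \cdot h_s)^2)}, clipped nonnegative and re-max-normalized. Because the
#' perturbation sd grows with the hierarchy value \eqn{h_s}, topographic
#' variability across simulated subjects increases toward transmodal
#' cortex, emulating the greater individual variability of association
#' cortex.
#'
#' @param groupV S x K group loading matrix.
#' @param hierarchy per-vertex hierarchy values in \[0, 1\].
#' @param topo_sd perturbation scale; 0 returns `groupV` unchanged.
#' @param seed integer RNG seed.
#' @return S x K nonnegative loading matrix, column max 1.
#' @export
personalizeGroundTruth <- function(groupV, hierarchy, topo_sd, seed = 1L) {
  stopifnot(nrow(groupV) == length(hierarchy))
  if (topo_sd == 0) return(groupV)
  eps <- with_seed(seed, {
    matrix(stats::rnorm(length(groupV)), nrow(groupV), ncol(groupV))
  })
  V <- groupV * pmax(0, 1 + eps * (topo_sd * hierarchy))
  max_normalize(V)$V
}

#' Synthetic cohort covariate table
#'
#' Ages uniform on `age_range`, sex Bernoulli(0.5), in-scanner motion
#' (mean framewise displacement, mm) lognormal, all reproducible by seed.
#'
#' @param n number of subjects.
#' @param age_range numeric length-2, years.
#' @param seed integer RNG seed.
#' @param motion_meanlog,motion_sdlog lognormal motion parameters; the
#'   defaults centre motion near 0.08 mm, typical of a quality-passed
#'   developmental sample.
#' @return data.frame with subject_id, age, sex, motion, ef (NA until
#'   [makeEfScores()] fills it).
#' @export
makeCohort <- function(n, age_range = c(8, 23), seed = 1L,
                       motion_meanlog = log(0.08), motion_sdlog = 0.4) {
  if (n == 0) {
    return(data.frame(subject_id = character(), age = numeric(),
                      sex = integer(), motion = numeric(), ef = numeric()))
  }
  with_seed(seed, {
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      age = stats::runif(n, age_range[1L], age_range[2L]),
      sex = stats::rbinom(n, 1L, 0.5),
      motion = stats::rlnorm(n, motion_meanlog, motion_sdlog),
      ef = NA_real_
    )
  })
}

# Planted edge-level coupling model at one scale. Hierarchy values are
# on the global [0,1] map scale, so hierarchical distances and pair
# means are comparable across scales. The per-edge age slope
#   b = age_slope * (1 - (h_A + h_B) - 1.5 * hd)
# is positive for hierarchically close unimodal pairs (both h small),
# negative for hierarchically distant pairs (the -1.5 hd term) and for
# transmodal pairs, so that network-level age effects decline along the
# hierarchy while edge-level age effects anti-correlate with
# hierarchical distance, both by construction.
planted_edge_model <- function(h_net, cfg) {
  K <- length(h_net)
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
  hd <- abs(h_net[pairs[, 1L]] - h_net[pairs[, 2L]])
  pm <- (h_net[pairs[, 1L]] + h_net[pairs[, 2L]]) / 2
  b <- cfg$age_slope * (1 - 2 * pm - 1.5 * hd)
  list(pairs = pairs, hdist = hd, pairmean = pm,
       intercept = cfg$rho0 - cfg$hdist_slope * hd, age_slope = b)
}

#' Planted between-network coupling matrix
#'
#' Evaluates the generator's edge-coupling model at one scale:
#' \eqn{\rho_e = \rho_0 - a \cdot d_e + b_e (age - age_0) + dev_e}, where
#' \eqn{d_e} is the normalized hierarchical distance of edge e and
#' \eqn{b_e} is positive for hierarchically close unimodal pairs and
#' negative for distant pairs. The assembled matrix (unit diagonal) is
#' repaired to the nearest valid correlation matrix by eigenvalue
#' clipping and re-normalization.
#'
#' @param model edge model for one scale, from the `truth` component of
#'   [simulateStudy()] (or [planted_edge_model] internally).
#' @param age subject age in years.
#' @param cfg generator configuration, see [syntheticConfig()].
#' @param dev optional per-edge subject deviations (upper-triangle order);
#'   default 0.
#' @return K x K valid correlation matrix (eigenvalues >= -1e-8).
#' @export
plantedCouplingMatrix <- function(model, age, cfg, dev = NULL) {
  rho <- model$intercept + model$age_slope * (age - cfg$age0)
  if (!is.null(dev)) rho <- rho + dev
  rho <- pmin(pmax(rho, -0.95), 0.95)
  K <- max(model$pairs)
  M <- diag(K)
  M[model$pairs] <- rho
  M[model$pairs[, c(2L, 1L)]] <- rho
  repair_correlation(M)
}

#' Simulate a BOLD-like subject timeseries
#'
#' Draws T samples of K network time courses with a target correlation
#' matrix (Gaussian, via Cholesky, plus a positive offset so courses are
#' BOLD-positive), mixes them onto vertices through the subject's loading
#' matrix, and adds vertex-level Gaussian noise:
#' \eqn{X = (Z + shift) V' + E}.
#'
#' @param V_i S x K subject loading matrix.
#' @param coupling_target K x K valid correlation matrix.
#' @param T_len number of timepoints.
#' @param noise_sd vertex noise sd (course sd units).
#' @param seed integer RNG seed.
#' @param course_shift additive offset on the unit-variance courses.
#' @return list with `data` (T x S matrix) and `courses` (T x K).
#' @export
simulateTimeseries <- function(V_i, coupling_target, T_len, noise_sd,
                               seed = 1L, course_shift = 3) {
  K <- ncol(V_i)
  stopifnot(all(dim(coupling_target) == c(K, K)))
  ev <- eigen(coupling_target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("coupling_target is not positive semidefinite")
  with_seed(seed, {
    Z <- matrix(stats::rnorm(T_len * K), T_len, K)
    ch <- chol(coupling_target + diag(1e-10, K))
    courses <- Z %*% ch + course_shift
    X <- courses %*% t(V_i)
    if (noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sd),
                      nrow(X), ncol(X))
    }
    list(data = X, courses = courses)
  })
}

#' Planted executive function scores
#'
#' EF is a seeded linear combination of edge couplings plus an age trend
#' and Gaussian noise. In the study-default wiring
#' ([simulateStudy()]), edge weights are negative for edges involving
#' networks at either hierarchy extreme and mildly positive for
#' mid-hierarchy edges, so that greater segregation of both sensorimotor
#' and default-mode-like networks predicts better EF.
#'
#' @param cohort cohort data.frame from [makeCohort()].
#' @param couplings subjects x edges numeric matrix of coupling values.
#' @param weights per-edge weight vector.
#' @param noise_sd EF noise sd (z units).
#' @param seed integer RNG seed.
#' @param age_slope EF change per year of age.
#' @return the cohort with the `ef` column filled.
#' @export
makeEfScores <- function(cohort, couplings, weights, noise_sd, seed = 1L,
                         age_slope = 0.1) {
  stopifnot(nrow(couplings) == nrow(cohort),
            ncol(couplings) == length(weights))
  ef <- as.numeric(couplings %*% weights) +
    age_slope * (cohort$age - mean(cohort$age))
  if (noise_sd > 0) {
    ef <- ef + with_seed(seed, stats::rnorm(nrow(cohort), sd = noise_sd))
  }
  cohort$ef <- ef
  cohort
}

# EF edge weight pattern from network hierarchy values: extremeness of a
# network is (2h'-1)^2 with h' the hierarchy value rescaled over the
# study's realized network range (`anchors`), so networks near either
# end of the achievable hierarchy are extreme; edges between extreme
# networks get negative weight, mid-hierarchy edges mildly positive.
# Returned unscaled; the caller normalizes the stacked weights to the
# target EF signal sd.
ef_edge_weights <- function(model, h_net, cfg, anchors = range(h_net)) {
  span <- max(anchors[2L] - anchors[1L], 1e-8)
  hn <- pmin(pmax((h_net - anchors[1L]) / span, 0), 1)
  extremeness <- (2 * hn - 1)^2
  w <- 0.35 - (extremeness[model$pairs[, 1L]] +
               extremeness[model$pairs[, 2L]]) / 2
  # EF loads on *selected* edges: those with a pronounced pattern weight
  # (segregation of hierarchy-extreme networks, integration of a few
  # mid-hierarchy pairs); weakly patterned edges carry no EF signal
  w[abs(w) < 0.25] <- 0
  w
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator: builds the mesh and hierarchy map, the nested
#' multi-scale group networks, per-subject personalized ground-truth
#' loadings, the cohort table with planted EF scores, per-scale planted
#' coupling models with stable subject deviations, and BOLD-like
#' timeseries generated from the `gen_scale` networks.
#'
#' @param cfg configuration list from [syntheticConfig()].
#' @return list with components `cfg`, `mesh`, `hierarchy`, `cohort`,
#'   `truth` (group/subject loadings, partitions, edge models, subject
#'   deviations, EF weights, per-subject target coupling matrices) and
#'   `timeseries` (list of T x S matrices).
#' @export
simulateStudy <- function(cfg = syntheticConfig()) {
  seeds <- derive_seeds(cfg$seed, 6L)
  mesh <- buildSphereMesh(cfg$subdivisions)
  hierarchy <- makeHierarchyMap(mesh, seed = seeds[1L],
                                noise_sd = cfg$hierarchy_noise,
                                smooth_iters = cfg$hierarchy_smooth)
  cohort <- makeCohort(cfg$n_subjects, cfg$age_range, seed = seeds[2L])
  n <- nrow(cohort)

  scales <- sort(unique(as.integer(c(cfg$scales, cfg$gen_scale))))
  truth <- list(group = list(), subject = list(), partition = list(),
                model = list(), dev = list(), h_net = list())
  subj_seeds <- matrix(derive_seeds(seeds[3L], n * length(scales)),
                       nrow = n)
  for (si in seq_along(scales)) {
    K <- scales[si]
    key <- as.character(K)
    gV <- makeGroupNetworks(mesh, K, seed = seeds[4L],
                            sharpness = cfg$kernel_sharpness)
    part <- argmax_row(gV)
    h_net <- vapply(seq_len(K), function(k) mean(hierarchy[part == k]),
                    numeric(1))
    truth$group[[key]] <- gV
    truth$partition[[key]] <- part
    truth$h_net[[key]] <- h_net
    truth$model[[key]] <- planted_edge_model(h_net, cfg)
    n_edges <- nrow(truth$model[[key]]$pairs)
    truth$dev[[key]] <- with_seed(seeds[5L] + K, {
      matrix(stats::rnorm(n * n_edges, sd = cfg$subject_dev_sd), n, n_edges)
    })
    truth$subject[[key]] <- lapply(seq_len(n), function(i) {
      personalizeGroundTruth(gV, hierarchy, cfg$topo_sd,
                             seed = subj_seeds[i, si])
    })
  }

  # per-subject target coupling matrices at every scale
  truth$target <- lapply(seq_along(scales), function(si) {
    K <- scales[si]; key <- as.character(K)
    lapply(seq_len(n), function(i) {
      plantedCouplingMatrix(truth$model[[key]], cohort$age[i], cfg,
                            dev = truth$dev[[key]][i, ])
    })
  })
  names(truth$target) <- as.character(scales)

  # EF from the gen-scale target couplings
  # EF is planted on the age-detrended couplings (the stable per-subject
  # edge deviations), so the EF-age relation is exactly ef_age_slope and
  # coupling-EF associations survive age control
  gkey <- as.character(cfg$gen_scale)
  model_g <- truth$model[[gkey]]
  w <- ef_edge_weights(model_g, truth$h_net[[gkey]], cfg)
  wnorm <- sqrt(sum(w^2) * cfg$subject_dev_sd^2)
  if (wnorm > 0) w <- w * cfg$ef_signal_sd / wnorm
  truth$ef_weights <- w
  truth$ef_scale <- cfg$gen_scale
  cohort <- makeEfScores(cohort, truth$dev[[gkey]], w, cfg$ef_noise_sd,
                         seed = seeds[6L], age_slope = cfg$ef_age_slope)

  ts_seeds <- derive_seeds(seeds[3L] + 1L, n)
  timeseries <- lapply(seq_len(n), function(i) {
    simulateTimeseries(truth$subject[[gkey]][[i]],
                       truth$target[[gkey]][[i]],
                       cfg$n_timepoints, cfg$noise_sd,
                       seed = ts_seeds[i],
                       course_shift = cfg$course_shift)$data
  })
  names(timeseries) <- cohort$subject_id

  list(cfg = cfg, mesh = mesh, hierarchy = hierarchy, cohort = cohort,
       truth = truth, timeseries = timeseries, scales = scales)
}

#' Simulate a coupling-level synthetic cohort
#'
#' Generator shortcut for the statistical stages: rather than simulating
#' timeseries and measuring coupling, it returns per-scale edge-coupling
#' observations equal to the planted subject targets plus Gaussian
#' sampling noise of sd `1.5/sqrt(T)` (the approximate standard error of
#' an averaged Pearson correlation at T timepoints). Used for calibration
#' and recovery studies of the inferential machinery at realistic sizes.
#'
#' @param cfg configuration list from [syntheticConfig()].
#' @return list with `cohort`, `hierarchy`, `h_net`, `model`, `edges`
#'   (long data.frame: subject, scale, edge id, netA, netB, coupling,
#'   hdist), `features` (subjects x all-scale edges matrix) and `truth`.
#' @export
simulateCouplingStudy <- function(cfg = syntheticConfig()) {
  seeds <- derive_seeds(cfg$seed, 6L)
  mesh <- buildSphereMesh(cfg$subdivisions)
  hierarchy <- makeHierarchyMap(mesh, seed = seeds[1L],
                                noise_sd = cfg$hierarchy_noise,
                                smooth_iters = cfg$hierarchy_smooth)
  cohort <- makeCohort(cfg$n_subjects, cfg$age_range, seed = seeds[2L])
  n <- nrow(cohort)
  noise_se <- 1.5 / sqrt(cfg$n_timepoints)

  scales <- sort(unique(as.integer(c(cfg$scales, cfg$gen_scale))))
  out <- list(model = list(), h_net = list(), dev = list())
  rows <- list()
  feats <- list()
  for (K in scales) {
    key <- as.character(K)
    gV <- makeGroupNetworks(mesh, K, seed = seeds[4L],
                            sharpness = cfg$kernel_sharpness)
    part <- argmax_row(gV)
    h_net <- vapply(seq_len(K), function(k) mean(hierarchy[part == k]),
                    numeric(1))
    model <- planted_edge_model(h_net, cfg)
    n_edges <- nrow(model$pairs)
    dev <- with_seed(seeds[5L] + K, {
      matrix(stats::rnorm(n * n_edges, sd = cfg$subject_dev_sd), n, n_edges)
    })
    target <- t(matrix(vapply(seq_len(n), function(i) {
      plantedCouplingMatrix(model, cohort$age[i], cfg,
                            dev = dev[i, ])[model$pairs]
    }, numeric(n_edges)), nrow = n_edges))
    obs <- target + with_seed(seeds[6L] + K, {
      matrix(stats::rnorm(n * n_edges, sd = noise_se), n, n_edges)
    })
    out$model[[key]] <- model
    out$h_net[[key]] <- h_net
    out$dev[[key]] <- dev
    colnames(obs) <- sprintf("s%d_e%d_%d", K,
                             model$pairs[, 1L], model$pairs[, 2L])
    feats[[key]] <- obs
    rows[[key]] <- data.frame(
      subject_id = rep(cohort$subject_id, each = n_edges),
      scale = K,
      netA = rep(model$pairs[, 1L], n),
      netB = rep(model$pairs[, 2L], n),
      hdist = rep(model$hdist, n),
      coupling = as.numeric(t(obs))
    )
  }

  # EF planted on the age-detrended couplings (stable subject edge
  # deviations) at every scale, with the hierarchy-extremeness weight
  # pattern anchored to the realized network-hierarchy range
  h_anchors <- range(unlist(out$h_net))
  w_all <- unlist(lapply(as.character(scales), function(key) {
    ef_edge_weights(out$model[[key]], out$h_net[[key]], cfg, h_anchors)
  }))
  dev_all <- do.call(cbind, lapply(as.character(scales), function(key) {
    out$dev[[key]]
  }))
  wnorm <- sqrt(sum(w_all^2) * cfg$subject_dev_sd^2)
  if (wnorm > 0) w_all <- w_all * cfg$ef_signal_sd / wnorm
  cohort <- makeEfScores(cohort, dev_all, w_all, cfg$ef_noise_sd,
                         seed = seeds[6L], age_slope = cfg$ef_age_slope)
  out$ef_weights <- w_all
  out$ef_target <- dev_all

  list(cohort = cohort, hierarchy = hierarchy, mesh = mesh,
       h_net = out$h_net, model = out$model, dev = out$dev,
       truth = out, scales = scales,
       edges = do.call(rbind, rows),
       features = do.call(cbind, feats))
}
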