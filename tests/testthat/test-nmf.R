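test_that("preprocessing shifts and scales each vertex into [0, 1]", {
  X <- cbind(c(-1, 0, 1), c(5, 5, 5), c(1, 2, 4))
  P <- preprocessForNmf(X)
  expect_equal(P[, 1L], c(0, 0.5, 1))
  expect_equal(P[, 2L], c(0, 0, 0))       # constant vertex guard
  expect_equal(P[, 3L], c(0, 1 / 3, 1))
  expect_error(preprocessForNmf(cbind(c(1, NA, 2))), "non-finite")
  expect_error(preprocessForNmf(matrix(1, 1, 3)), "2 timepoints")
})

test_that("affinity uses (1+corr)/2 on mesh edges only", {
  mesh <- small_mesh()
  nb <- neighborLists(mesh)
  S <- nVertices(mesh)
  base <- sin(seq_len(20))
  X <- matrix(rnorm(20 * S), 20, S)
  X[, 1L] <- base
  X[, nb[[1L]][1L]] <- 2 * base + 3        # corr +1 with vertex 1
  X[, nb[[1L]][2L]] <- -base               # corr -1 with vertex 1
  X[, nb[[1L]][3L]] <- 7                   # zero-variance vertex
  af <- buildAffinity(mesh, X)
  expect_equal(af$W[1L, nb[[1L]][1L]], 1)
  expect_equal(af$W[1L, nb[[1L]][2L]], 0)
  expect_equal(af$W[1L, nb[[1L]][3L]], 0.5)  # uninformative limit
  non_nb <- setdiff(seq_len(S), c(1L, nb[[1L]]))
  expect_true(all(af$W[1L, non_nb] == 0))
  expect_equal(as.matrix(af$W), t(as.matrix(af$W)))
  ev <- eigen(as.matrix(af$L), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("the consensus penalty matches its closed form", {
  expect_equal(consensusPenalty(list(matrix(c(1, 0, 0, 0), ncol = 1))), 1)
  expect_equal(consensusPenalty(list(matrix(rep(0.3, 4), ncol = 1))), 2)
  V <- matrix(runif(12), 4, 3)
  expect_equal(consensusPenalty(list(V)), consensusPenalty(list(5 * V)))
  # multi-subject value against a direct evaluation of the formula
  Vs <- withr::with_seed(1, replicate(3, matrix(runif(10), 5, 2),
                                      simplify = FALSE))
  direct <- 0
  for (k in 1:2) {
    sq <- sapply(Vs, function(V) V[, k]^2)
    direct <- direct + sum(sqrt(rowSums(sq))) / sqrt(sum(sq))
  }
  expect_equal(consensusPenalty(Vs), direct)
  expect_equal(consensusPenalty(list(matrix(0, 4, 1))), 0)
})

test_that("the locality penalty is the weighted edge roughness", {
  L2 <- matrix(c(1, -1, -1, 1), 2, 2)          # two vertices, W = 1
  expect_equal(localityPenalty(matrix(c(1, 0), ncol = 1), L2), 1)
  expect_equal(localityPenalty(matrix(c(3, 3), ncol = 1), L2), 0)
  # an isolated vertex leaves the value unchanged
  L3 <- rbind(cbind(L2, 0), 0)
  expect_equal(localityPenalty(matrix(c(1, 0, 5), ncol = 1), L3), 1)
})

test_that("regularization weights follow the stated scaling rules", {
  w <- regularizationWeights(nmfConfig(5, alpha = 1, beta = 10), n = 2,
                             T_len = 10, n_m = 4)
  expect_equal(w$lambda_c, 4)       # alpha * n * T / K
  expect_equal(w$lambda_M, 5)       # beta * T / (K * n_m)
  expect_equal(regularizationWeights(nmfConfig(5, alpha = 0), 2, 10, 4)$lambda_c, 0)
})

test_that("the joint objective equals its independently computed terms", {
  withr::with_seed(2, {
    Xs <- replicate(2, matrix(runif(60), 10, 6), simplify = FALSE)
    Us <- replicate(2, matrix(runif(30), 10, 3), simplify = FALSE)
    Vs <- replicate(2, matrix(runif(18), 6, 3), simplify = FALSE)
    W <- matrix(runif(36), 6, 6); W <- (W + t(W)) / 2; diag(W) <- 0
    L <- diag(rowSums(W)) - W
    Ls <- list(L, L)
  })
  obj <- nmfObjective(Xs, Us, Vs, Ls, lambda_M = 2.5, lambda_c = 1.5)
  recon <- sum((Xs[[1]] - Us[[1]] %*% t(Vs[[1]]))^2) +
    sum((Xs[[2]] - Us[[2]] %*% t(Vs[[2]]))^2)
  loc <- localityPenalty(Vs[[1]], L) + localityPenalty(Vs[[2]], L)
  expect_equal(obj, recon + 2.5 * loc + 1.5 * consensusPenalty(Vs))
  # exact factorization with zero weights gives zero
  X0 <- Us[[1]] %*% t(Vs[[1]])
  expect_equal(nmfObjective(list(X0), Us[1], Vs[1], Ls[1], 0, 0), 0)
})

test_that("group NMF recovers planted factors and satisfies its contracts", {
  L0 <- Matrix::Diagonal(30) * 0
  for (s in 1:3) {
    planted <- withr::with_seed(s, {
      list(U = matrix(runif(40 * 3), 40, 3), V = matrix(runif(90), 30, 3))
    })
    X <- planted$U %*% t(planted$V)
    fit <- fitGroupNmf(X, L0, nmfConfig(3, alpha = 0, beta = 0,
                                        max_iter = 4000, tol = 1e-13,
                                        seed = s))
    relerr <- norm(X - fit$U %*% t(fit$V), "F") / norm(X, "F")
    expect_lt(relerr, 1e-3)
    expect_equal(unname(apply(fit$V, 2, max)), rep(1, 3))
    expect_true(all(diff(fit$objective) <= 1e-10 * pmax(head(fit$objective, -1), 1)))
    expect_true(all(fit$U >= 0) && all(fit$V >= 0))
  }
  expect_error(fitGroupNmf(matrix(-1, 10, 5), L0[1:5, 1:5], nmfConfig(2)),
               "nonnegative")
  expect_error(fitGroupNmf(matrix(1, 4, 5), L0[1:5, 1:5], nmfConfig(5)),
               "exceeds")
})

test_that("the joint multi-subject model honours its limits", {
  mesh <- small_mesh()
  V0 <- makeGroupNetworks(mesh, 3, seed = 1)
  Sig <- diag(3) * 0.6 + 0.4
  ts <- simulateTimeseries(V0, Sig, 120, 0.05, seed = 4)
  X <- preprocessForNmf(ts$data)
  L <- buildAffinity(mesh, X)$L

  # consensus-dominated limit: identical data, jittered inits agree
  inits <- withr::with_seed(9, lapply(1:3, function(i) {
    pmax(V0 * matrix(runif(42 * 3, 0.5, 1.5), 42, 3), 1e-6)
  }))
  fitC <- fitMultisubjectNmf(list(X, X, X), list(L, L, L),
                             nmfConfig(3, alpha = 200, beta = 10,
                                       max_iter = 200, seed = 2),
                             init_V = inits)
  expect_lt(max(abs(fitC[[1]]$V - fitC[[2]]$V)), 1e-3)
  expect_lt(max(abs(fitC[[1]]$V - fitC[[3]]$V)), 1e-3)
  for (f in fitC) {
    expect_true(all(f$V >= 0))
    expect_equal(unname(apply(f$V, 2, max)), rep(1, 3))
  }

  # with alpha = 0 a single subject reduces to the group solver
  cfg0 <- nmfConfig(3, alpha = 0, beta = 10, max_iter = 80, tol = 1e-9,
                    seed = 2)
  init <- list(U = matrix(0.5, 120, 3), V = matrix(0.5, 42, 3))
  g <- fitGroupNmf(X, L, cfg0, init = init)
  ms <- fitMultisubjectNmf(list(X), list(L), cfg0, init_V = matrix(0.5, 42, 3))
  expect_lt(max(abs(g$V - ms[[1]]$V)), 1e-3)

  expect_error(fitMultisubjectNmf(list(X, X[, 1:10]), list(L, L),
                                  nmfConfig(3), init_V = V0),
               "vertex count")
})

test_that("the locality weight produces spatially smoother loadings", {
  mesh <- small_mesh()
  V0 <- makeGroupNetworks(mesh, 3, seed = 1)
  Sig <- diag(3) * 0.6 + 0.4
  ts <- simulateTimeseries(V0, Sig, 100, 0.2, seed = 5)
  X <- preprocessForNmf(ts$data)
  L <- buildAffinity(mesh, X)$L
  rough10 <- rough0 <- numeric(5)
  for (s in 1:5) {
    f10 <- fitGroupNmf(X, L, nmfConfig(3, alpha = 1, beta = 10,
                                       max_iter = 150, seed = s))
    f0 <- fitGroupNmf(X, L, nmfConfig(3, alpha = 1, beta = 0,
                                      max_iter = 150, seed = s))
    rough10[s] <- localityPenalty(f10$V, L)
    rough0[s] <- localityPenalty(f0$V, L)
  }
  expect_lt(mean(rough10), mean(rough0))
})

test_that("the group pathway recovers planted networks", {
  study <- simulateStudy(syntheticConfig(scales = c(2L, 4L), seed = 7L,
                                         topo_sd = 0, n_subjects = 16L,
                                         n_timepoints = 300L))
  Xp <- lapply(study$timeseries, preprocessForNmf)
  Lg <- buildAffinity(study$mesh, do.call(rbind, Xp))$L
  reps <- bootstrapGroupAtlases(Xp, Lg,
                                nmfConfig(4, max_iter = 250, tol = 1e-7,
                                          seed = 3),
                                n_subset = 8, n_reps = 6, seed = 5)
  atlas <- fuseAtlases(reps, 4, seed = 6)
  mc <- matchNetworks(study$truth$group[["4"]], atlasLoadings(atlas))
  expect_gte(mean(mc$correlations), 0.8)
})
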