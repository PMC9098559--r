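test_that("network similarity follows the Gaussian kernel of distances", {
  withr::with_seed(1, {
    base <- matrix(runif(40 * 3), 40, 3)
  })
  sim <- networkSimilarity(cbind(base, base))
  # identical networks: distance 0, similarity 1
  expect_equal(sim$d[1L, 4L], 0)
  expect_equal(sim$S_sim[1L, 4L], 1)
  expect_true(all(diag(sim$S_sim) == 1))
  expect_equal(sim$S_sim, t(sim$S_sim))
  # a pair at exactly the median distance has similarity exp(-1)
  idx <- which(abs(sim$d - sim$sigma) < 1e-12, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    expect_equal(sim$S_sim[idx[1L, 1L], idx[1L, 2L]], exp(-1))
  }
  # anti-correlated loadings: d = 2, S = exp(-4 / sigma^2)
  x <- runif(30)
  sim2 <- networkSimilarity(cbind(x, 1 - x, runif(30)))
  expect_equal(sim2$d[1L, 2L], 2)
  expect_equal(sim2$S_sim[1L, 2L], exp(-4 / sim2$sigma^2))
})

test_that("fusion recovers planted network families", {
  withr::with_seed(3, {
    famA <- runif(60); famB <- runif(60)
    atlases <- lapply(1:5, function(r) {
      V <- cbind(famA + rnorm(60, 0, 0.02), famB + rnorm(60, 0, 0.02))
      pmax(V, 0)
    })
  })
  fused <- fuseAtlases(atlases, 2, seed = 4)
  expect_s4_class(fused, "GroupAtlas")
  expect_equal(ncol(atlasLoadings(fused)), 2L)
  mc <- matchNetworks(pmax(cbind(famA, famB), 0), atlasLoadings(fused))
  expect_true(all(mc$correlations >= 0.95))

  # n identical atlases: representatives equal inputs up to column order
  same <- replicate(4, pmax(cbind(famA, famB), 0), simplify = FALSE)
  fused2 <- fuseAtlases(same, 2, seed = 5)
  mc2 <- matchNetworks(same[[1L]] / rep(apply(same[[1L]], 2, max),
                                        each = 60),
                       atlasLoadings(fused2))
  expect_true(all(mc2$correlations > 1 - 1e-12))
})

test_that("fusion is stable across spectral seeds", {
  withr::with_seed(11, {
    fams <- matrix(runif(50 * 3), 50, 3)
    atlases <- lapply(1:6, function(r) pmax(fams + rnorm(150, 0, 0.05), 0))
  })
  f1 <- fuseAtlases(atlases, 3, seed = 1)
  f2 <- fuseAtlases(atlases, 3, seed = 99)
  mc <- matchNetworks(atlasLoadings(f1), atlasLoadings(f2))
  expect_gte(mean(mc$correlations), 0.95)
})

test_that("personalization adapts the atlas to the subject's data", {
  mesh <- small_mesh()
  V0 <- makeGroupNetworks(mesh, 3, seed = 2)
  Sig <- diag(3) * 0.65 + 0.35
  # derive an atlas by fitting the model itself, then generate a fresh
  # subject exactly from that atlas: personalization must reproduce it
  ts0 <- simulateTimeseries(V0, Sig, 300, 0.02, seed = 7)
  X0 <- preprocessForNmf(ts0$data)
  L0 <- buildAffinity(mesh, X0)$L
  gfit <- fitGroupNmf(X0, L0, nmfConfig(3, max_iter = 300, tol = 1e-8,
                                        seed = 4))
  atlas <- new("GroupAtlas", loadings = gfit$V, scale = 3L,
               provenance = rep(1L, 3))
  ts <- simulateTimeseries(gfit$V, Sig, 300, 0.02, seed = 8)
  X <- preprocessForNmf(ts$data)
  L <- buildAffinity(mesh, X)$L
  cfg <- nmfConfig(3, max_iter = 100, seed = 2)
  Vp <- personalizeNetworks(X, L, atlas, cfg)
  mt <- matchNetworks(atlasLoadings(atlas), Vp)
  # subject data generated exactly from the atlas: high self-consistency,
  # and best-match ordering is the identity (correspondence preserved)
  expect_true(all(mt$correlations >= 0.95))
  expect_equal(mt$perm, 1:3)
  expect_true(all(Vp >= 0))
  expect_equal(unname(apply(Vp, 2, max)), rep(1, 3))
  # max_iter = 0 returns the initialization untouched
  cfg0 <- nmfConfig(3, max_iter = 0, seed = 2)
  expect_identical(personalizeNetworks(X, L, atlas, cfg0),
                   atlasLoadings(atlas))
})

test_that("hard partitions use argmax with deterministic tie-breaking", {
  V <- rbind(c(0.2, 0.7, 0.1), c(0.5, 0.5, 0.1), c(0, 0, 0))
  labs <- hardPartition(V)
  expect_equal(labs[1L], 2L)
  expect_equal(labs[2L], 1L)        # tie toward the lowest index
  expect_true(is.na(labs[3L]))      # all-zero row unassigned
})

test_that("nestedness summarises plurality overlap with the K=2 partition", {
  p2 <- rep(c(1L, 2L), each = 10)
  pK <- c(rep(1L, 5), rep(2L, 5), rep(3L, 5), rep(4L, 5))
  out <- nestednessVsK2(p2, pK)
  expect_equal(out$per_network$parent, c(1L, 1L, 2L, 2L))
  expect_true(all(out$per_network$overlap == 1))
  expect_equal(sum(out$summary), 100)
  # exact 50/50 split: parent is the lower label with fraction 0.5
  pK2 <- rep(1L, 20)
  out2 <- nestednessVsK2(p2, pK2)
  expect_equal(out2$per_network$parent, 1L)
  expect_equal(out2$per_network$overlap, 0.5)
})

test_that("the adjusted Rand index matches its contingency formula", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # hand-evaluated 2x2 case: all contingency cells 1
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # independent cross-check against mclust on random partitions
  skip_if_not_installed("mclust")
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- sample(1:4, 60, replace = TRUE)
      b <- sample(1:3, 60, replace = TRUE)
      expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b))
    }
  })
})

test_that("Hungarian matching agrees with brute-force enumeration", {
  withr::with_seed(6, {
    for (i in 1:5) {
      A <- matrix(runif(80), 20, 4)
      B <- matrix(runif(80), 20, 4)
      mt <- matchNetworks(A, B)
      bf <- brute_match(A, B)
      expect_equal(mt$perm, bf$perm)
      expect_equal(sum(mt$correlations), bf$total)
    }
  })
})

test_that("decompositions are more similar within than between subjects", {
  mesh <- small_mesh()
  h <- makeHierarchyMap(mesh, seed = 3)
  V0 <- makeGroupNetworks(mesh, 3, seed = 2)
  atlas <- new("GroupAtlas", loadings = V0, scale = 3L,
               provenance = rep(1L, 3))
  Sig <- diag(3) * 0.6 + 0.4
  subjects <- lapply(1:3, function(i) {
    Vi <- personalizeGroundTruth(V0, h, 0.6, seed = 40 + i)
    ts <- simulateTimeseries(Vi, Sig, 200, 0.05, seed = 50 + i)
    X <- preprocessForNmf(ts$data)
    list(X = X, L = buildAffinity(mesh, X)$L)
  })
  partitions <- lapply(subjects, function(s) {
    lapply(c(5, 10), function(beta) {
      cfg <- nmfConfig(3, beta = beta, max_iter = 60, seed = 2)
      hardPartition(personalizeNetworks(s$X, s$L, atlas, cfg))
    })
  })
  within <- vapply(partitions, function(p) adjustedRand(p[[1]], p[[2]]),
                   numeric(1))
  between <- c(adjustedRand(partitions[[1]][[1]], partitions[[2]][[1]]),
               adjustedRand(partitions[[2]][[1]], partitions[[3]][[1]]),
               adjustedRand(partitions[[1]][[1]], partitions[[3]][[1]]))
  expect_gt(mean(within), mean(between))
})
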