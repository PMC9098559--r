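test_that("hierarchy map is a rescaled z-gradient plus smooth noise", {
  mesh <- small_mesh()
  h0 <- makeHierarchyMap(mesh, seed = 1, noise_sd = 0)
  z <- vertexCoords(mesh)[, 3L]
  expect_equal(h0, (z - min(z)) / (max(z) - min(z)))
  h1 <- makeHierarchyMap(mesh, seed = 3)
  expect_identical(h1, makeHierarchyMap(mesh, seed = 3))
  expect_true(all(h1 >= 0 & h1 <= 1))
  # spatial autocorrelation exceeds that of a shuffled map
  ac <- pfnets:::neighbor_autocorrelation(h1, neighborLists(mesh))
  shuf <- withr::with_seed(9, replicate(50, {
    pfnets:::neighbor_autocorrelation(sample(h1), neighborLists(mesh))
  }))
  expect_gt(ac, max(shuf))
})

test_that("planted group networks are nested, contiguous soft parcels", {
  mesh <- desk_mesh()
  V2 <- makeGroupNetworks(mesh, 2, seed = 1)
  V4 <- makeGroupNetworks(mesh, 4, seed = 1)
  expect_equal(unname(apply(V2, 2, max)), c(1, 1))
  expect_equal(unname(apply(V4, 2, max)), rep(1, 4))
  expect_true(all(V4 >= 0))
  p2 <- hardPartition(V2); p4 <- hardPartition(V4)
  expect_setequal(unique(p2), 1:2)
  # every K=4 network predominantly inside one K=2 half
  nest <- nestednessVsK2(p2, p4)
  expect_true(all(nest$per_network$overlap >= 0.9))
  expect_equal(sum(nest$summary), 100)
})

test_that("topographic perturbation scales with the hierarchy", {
  mesh <- desk_mesh()
  V <- makeGroupNetworks(mesh, 4, seed = 1)
  h <- makeHierarchyMap(mesh, seed = 2)
  expect_identical(personalizeGroundTruth(V, h, 0, seed = 1), V)
  Vs <- lapply(1:50, function(i) personalizeGroundTruth(V, h, 0.5, seed = i))
  expect_true(all(vapply(Vs, function(x) all(x >= 0), logical(1))))
  expect_true(all(vapply(Vs, function(x) max(abs(apply(x, 2, max) - 1)) < 1e-12,
                         logical(1))))
  # vertex-wise dispersion across subjects increases along the hierarchy
  arr <- simplify2array(Vs)                  # S x K x 50
  disp <- rowMeans(apply(arr, c(1L, 2L), sd))  # across-subject dispersion
  ct <- cor.test(disp, h, alternative = "greater")
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("cohort tables honour their configuration and seed", {
  expect_equal(nrow(makeCohort(0)), 0L)
  coh <- makeCohort(30, age_range = c(8, 23), seed = 4)
  expect_true(all(coh$age >= 8 & coh$age <= 23))
  expect_true(all(coh$motion > 0))
  expect_true(all(coh$sex %in% 0:1))
  expect_identical(coh, makeCohort(30, age_range = c(8, 23), seed = 4))
})

test_that("planted coupling matrices are valid and hierarchy-patterned", {
  mesh <- desk_mesh()
  cfg <- syntheticConfig()
  h <- makeHierarchyMap(mesh, seed = 2)
  part <- hardPartition(makeGroupNetworks(mesh, 5, seed = 1))
  h_net <- vapply(1:5, function(k) mean(h[part == k]), numeric(1))
  model <- pfnets:::planted_edge_model(h_net, cfg)
  M0 <- plantedCouplingMatrix(model, cfg$age0, cfg)
  # at the reference age the matrix equals the repaired intercept model
  Mint <- diag(5); Mint[model$pairs] <- model$intercept
  Mint[model$pairs[, c(2, 1)]] <- model$intercept
  expect_equal(M0, pfnets:::repair_correlation(Mint))
  expect_true(all(diag(M0) == 1))
  ev <- eigen(plantedCouplingMatrix(model, 22, cfg,
                                    dev = rep(0.1, nrow(model$pairs))),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # age slopes anti-correlate with hierarchical distance by construction
  expect_lt(cor(model$age_slope, model$hdist), 0)
})

test_that("simulated timeseries realize the target coupling", {
  mesh <- small_mesh()
  V1 <- matrix(runif(42), ncol = 1)
  ts <- simulateTimeseries(V1, matrix(1, 1, 1), 50, 0, seed = 1)
  # single network, no noise: every vertex proportional to the course
  cors <- suppressWarnings(cor(ts$data, ts$courses))
  expect_true(all(abs(cors[V1 > 1e-12]) > 1 - 1e-12))
  expect_identical(simulateTimeseries(V1, matrix(1, 1, 1), 50, 0.3, seed = 2),
                   simulateTimeseries(V1, matrix(1, 1, 1), 50, 0.3, seed = 2))
  # course-correlation fidelity at T = 555 over replicates
  Sig <- matrix(c(1, .4, .1, .4, 1, .25, .1, .25, 1), 3, 3)
  devs <- vapply(1:200, function(r) {
    sim <- simulateTimeseries(matrix(runif(42 * 3), 42, 3), Sig, 555, 0,
                              seed = 1000 + r)
    mean(abs(cor(sim$courses) - Sig)[upper.tri(Sig)])
  }, numeric(1))
  expect_lt(mean(devs), 2 / sqrt(555))
  expect_error(simulateTimeseries(V1, matrix(-1, 1, 1), 10, 0, seed = 1),
               "positive semidefinite")
})

test_that("planted EF scores are a recoverable coupling combination", {
  coh <- makeCohort(60, seed = 2)
  C <- withr::with_seed(3, matrix(rnorm(60 * 8, sd = 0.12), 60, 8))
  w <- c(1.2, -0.8, 0.5, 0, 0, 0.3, -0.4, 0.9)
  # zero weights and zero noise leave the pure age trend
  coh0 <- makeEfScores(coh, C, rep(0, 8), 0, seed = 1, age_slope = 0.1)
  expect_equal(coh0$ef, 0.1 * (coh$age - mean(coh$age)))
  # noiseless EF is recovered by regression on the true edges
  coh1 <- makeEfScores(coh, C, w, 0, seed = 1, age_slope = 0.1)
  fit <- lm(coh1$ef ~ C + coh$age)
  expect_gt(cor(fitted(fit), coh1$ef), 0.95)
  expect_identical(makeEfScores(coh, C, w, 0.4, seed = 7)$ef,
                   makeEfScores(coh, C, w, 0.4, seed = 7)$ef)
})

test_that("the study generators are deterministic given config and seed", {
  cfg <- syntheticConfig(seed = 12L, n_subjects = 6L, subdivisions = 1L,
                         n_timepoints = 60L, scales = c(2L, 3L),
                         gen_scale = 3L)
  a <- simulateCouplingStudy(cfg)
  b <- simulateCouplingStudy(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$cohort, b$cohort)
  sa <- simulateStudy(cfg)
  sb <- simulateStudy(cfg)
  expect_identical(sa$timeseries, sb$timeseries)
  expect_identical(sa$cohort$ef, sb$cohort$ef)
})
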