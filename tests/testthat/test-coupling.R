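test_that("edge coupling equals the brute-force pair average", {
  # hand toy: 3 timepoints, 2 + 2 vertices
  X <- cbind(c(1, 2, 3), c(1, 3, 2), c(3, 2, 1), c(2, 2.5, 1))
  labels <- c(1L, 1L, 2L, 2L)
  E <- edgeCoupling(X, labels)
  pairs_mean <- mean(c(cor(X[, 1], X[, 3]), cor(X[, 1], X[, 4]),
                       cor(X[, 2], X[, 3]), cor(X[, 2], X[, 4])))
  expect_equal(E[1L, 2L], pairs_mean)
  expect_equal(E, t(E))
  expect_equal(E[1L, 1L], cor(X[, 1], X[, 2]))   # within-network mean

  # two singleton networks sharing a timeseries couple at exactly 1
  X2 <- cbind(c(1, 2, 3), c(2, 4, 6))
  expect_equal(edgeCoupling(X2, c(1L, 2L))[1L, 2L], 1)

  # naive double loop oracle on a larger random instance
  withr::with_seed(4, {
    Xr <- matrix(rnorm(20 * 12), 20, 12)
    lr <- sample(1:3, 12, replace = TRUE)
  })
  Er <- edgeCoupling(Xr, lr, 3)
  C <- cor(Xr)
  for (A in 1:2) for (B in (A + 1):3) {
    acc <- c()
    for (a in which(lr == A)) for (b in which(lr == B)) {
      acc <- c(acc, C[a, b])
    }
    expect_equal(Er[A, B], mean(acc), tolerance = 1e-12)
  }
  # empty network propagates NA
  E3 <- edgeCoupling(Xr, ifelse(lr == 3L, 1L, lr), 3)
  expect_true(all(is.na(E3[3L, ])))
})

test_that("network coupling is the off-diagonal row mean", {
  E <- rbind(c(NA, 0.2, 0.4), c(0.2, NA, 0.1), c(0.4, 0.1, NA))
  diag(E) <- c(0.9, 0.8, 0.7)
  expect_equal(networkCoupling(E), c(0.3, 0.15, 0.25))
  E2 <- matrix(c(0.5, 0.3, 0.3, 0.6), 2, 2)
  expect_equal(networkCoupling(E2), c(0.3, 0.3))
  # permutation equivariance
  withr::with_seed(2, {
    Xr <- matrix(rnorm(30 * 9), 30, 9)
    lr <- rep(1:3, each = 3)
  })
  nc <- networkCoupling(edgeCoupling(Xr, lr, 3))
  perm <- c(3L, 1L, 2L)
  nc_p <- networkCoupling(edgeCoupling(Xr, perm[lr], 3))
  expect_equal(nc_p[perm], nc)
})

test_that("vertex coupling averages only out-of-network correlations", {
  # 3 vertices, 2 networks: direct enumeration
  X <- cbind(c(1, 2, 4), c(2, 1, 3), c(0, 1, 2))
  labels <- c(1L, 1L, 2L)
  vc <- vertexCoupling(X, labels)
  expect_equal(vc[1L], cor(X[, 1], X[, 3]))
  expect_equal(vc[2L], cor(X[, 2], X[, 3]))
  expect_equal(vc[3L], mean(c(cor(X[, 3], X[, 1]), cor(X[, 3], X[, 2]))))
  # all vertices sharing one series couple at 1
  Xs <- cbind(c(1, 2, 3), c(2, 4, 6), c(0.5, 1, 1.5))
  expect_equal(vertexCoupling(Xs, c(1L, 2L, 2L)), rep(1, 3))
  # own-network vertices are excluded from the average
  X2 <- X; X2[, 2L] <- rev(X2[, 2L])   # change own-network partner of v1
  expect_equal(vertexCoupling(X2, labels)[1L], vc[1L])
})

test_that("computeCoupling assembles a consistent CouplingSet", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    labels <- rep(1:2, each = 5)
  })
  cs <- computeCoupling(X, labels, 2, subject_id = "sub-001")
  expect_s4_class(cs, "CouplingSet")
  expect_equal(networkCouplingOf(cs), networkCoupling(edgeMatrix(cs)))
  expect_true(all(abs(vertexCouplingOf(cs)) <= 1))
  expect_output(show(cs), "sub-001")
})

test_that("network hierarchy values average the map over the partition", {
  hv <- networkHierarchyValues(c(1L, 1L, 2L), c(1, 3, 5))
  expect_equal(hv$network, c(2, 5))
  expect_equal(hv$edge_distance[1L, 2L], 3)
  expect_equal(networkHierarchyValues(rep(1L, 3), c(1, 3, 5))$network, 3)
  expect_equal(hv$edge_distance[1L, 1L], 0)
})

test_that("Euclidean edge distance averages member pair distances", {
  mesh <- small_mesh()
  # antipodal singletons on the real mesh
  z <- vertexCoords(mesh)[, 3L]
  top <- which.max(z); bottom <- which.min(z)
  labels <- rep(NA_integer_, nVertices(mesh))
  labels[top] <- 1L; labels[bottom] <- 2L
  D <- euclideanEdgeDistance(mesh, labels)
  expect_equal(D[1L, 2L], sqrt(sum((vertexCoords(mesh)[top, ] -
                                    vertexCoords(mesh)[bottom, ])^2)))
  # coincident networks at distance 0 and brute-force 3 + 3 check
  withr::with_seed(8, {
    lab2 <- rep(NA_integer_, nVertices(mesh))
    iA <- sample(nVertices(mesh), 3); iB <- sample(setdiff(seq_len(nVertices(mesh)), iA), 3)
    lab2[iA] <- 1L; lab2[iB] <- 2L
  })
  D2 <- euclideanEdgeDistance(mesh, lab2)
  acc <- c()
  for (a in iA) for (b in iB) {
    acc <- c(acc, sqrt(sum((vertexCoords(mesh)[a, ] - vertexCoords(mesh)[b, ])^2)))
  }
  expect_equal(D2[1L, 2L], mean(acc))
})

test_that("MAD maps quantify cross-subject loading variability", {
  V <- matrix(runif(20), 10, 2)
  expect_equal(madMap(list(V, V, V))$mad, rep(0, 10))
  # two-point check at one vertex: loadings {0, 1} give MAD 0.5
  Va <- matrix(0, 4, 1); Vb <- matrix(1, 4, 1)
  expect_equal(madMap(list(Va, Vb, Va, Vb))$mad, rep(0.5, 4))
  withr::with_seed(1, {
    Vs <- replicate(8, matrix(runif(30), 15, 2), simplify = FALSE)
  })
  mm <- madMap(Vs)
  expect_true(all(mm$mad >= 0))
  expect_equal(mean(mm$z), 0, tolerance = 1e-12)
  expect_equal(sd(mm$z), 1, tolerance = 1e-12)
  expect_error(madMap(list(V, V)), "3 subjects")
})

test_that("measured edge coupling tracks the planted targets", {
  cfg <- syntheticConfig()
  mesh <- desk_mesh()
  h <- makeHierarchyMap(mesh, seed = 2)
  V <- makeGroupNetworks(mesh, 4, seed = 1)
  lab <- hardPartition(V)
  h_net <- vapply(1:4, function(k) mean(h[lab == k]), numeric(1))
  model <- pfnets:::planted_edge_model(h_net, cfg)
  withr::with_seed(1, {
    targets <- c(); meas <- c()
    for (r in 1:20) {
      age <- runif(1, 8, 23)
      Sig <- plantedCouplingMatrix(model, age, cfg,
                                   dev = rnorm(6, sd = cfg$subject_dev_sd))
      ts <- simulateTimeseries(V, Sig, 555, cfg$noise_sd,
                               seed = sample.int(1e6, 1))
      E <- edgeCoupling(scale(ts$data), lab, 4)
      targets <- c(targets, Sig[upper.tri(Sig)])
      meas <- c(meas, E[upper.tri(E)])
    }
  })
  slope <- coef(lm(meas ~ targets))[[2L]]
  expect_gte(slope, 0.9)
  expect_lte(slope, 1.1)
  expect_true(all(abs(meas) <= 1))
})
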