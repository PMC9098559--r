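# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_mesh <- function() cached("mesh1", function() buildSphereMesh(1L))
desk_mesh <- function() cached("mesh2", function() buildSphereMesh(2L))

# smooth scalar field on a mesh (for spin tests etc.)
smooth_field <- function(mesh, seed, iters = 8L) {
  v <- withr::with_seed(seed, stats::rnorm(nVertices(mesh)))
  nb <- neighborLists(mesh)
  for (i in seq_len(iters)) {
    v <- vapply(seq_along(v), function(s) mean(v[c(s, nb[[s]])]), numeric(1))
  }
  v
}

# default coupling-level study used by several statistical tests
desk_coupling_study <- function() {
  cached("cstudy", function() {
    simulateCouplingStudy(syntheticConfig(seed = 5L, n_subjects = 150L))
  })
}

# small covariate frame for GAM/GEE tests
sim_covariates <- function(n, seed = 1L) {
  withr::with_seed(seed, data.frame(
    age = stats::runif(n, 8, 23),
    sex = stats::rbinom(n, 1L, 0.5),
    motion = stats::rlnorm(n, log(0.08), 0.4)
  ))
}

# brute-force best-assignment column correlation by permutation search
brute_match <- function(A, B) {
  K <- ncol(A)
  cc <- stats::cor(A, B)
  perms <- gtools_permutations(K)
  best <- -Inf; best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    tot <- sum(cc[cbind(seq_len(K), perms[i, ])])
    if (tot > best) { best <- tot; best_perm <- perms[i, ] }
  }
  list(perm = unname(best_perm), total = best)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
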