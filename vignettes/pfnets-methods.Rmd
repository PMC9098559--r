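---
title: "Multi-scale personalized functional networks: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale personalized functional networks: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`pfnets` implements a complete analysis chain for studying how
personalized functional brain networks, defined at many scales
(numbers of networks K), develop across adolescence and relate to
executive function (EF):

1. spatially regularized, group-consensus non-negative matrix
   factorization (NMF) of surface fMRI timeseries;
2. bootstrap construction of a group atlas fused by spectral
   clustering, and per-subject personalization of that atlas;
3. between-network coupling at network, edge and vertex level, plus
   topographic-variability (MAD) maps;
4. penalized-spline (GAM) age and EF models with signed
   adjusted-R-squared effect sizes, hierarchy and hierarchical-distance
   regressions with bootstrap inference, generalized estimating
   equations (GEE) across scales, and spherical spin tests;
5. ridge prediction of EF from multi-scale coupling with nested
   split-thirds tuning and permutation inference.

Real developmental neuroimaging cohorts are access-restricted, so the
package ships a synthetic-data generator that emulates the *structure*
of such data. Every stage is validated end-to-end against the
generator's planted ground truth.

# The factorization model

A subject's preprocessed timeseries is a T x S matrix X (time by
vertex) on a spherical surface mesh. We seek nonnegative time courses
U (T x K) and loadings V (S x K) with X close to U V'. Nonnegativity
yields a parts-based decomposition in which each column of V is one
functional network and the loading quantifies how much a vertex
belongs to it. Three terms are combined:

* **Reconstruction**: squared Frobenius error per subject.
* **Data locality**: Tr(V' L V), with L the graph Laplacian of a sparse
  affinity built only on mesh edges, affinity (1 + corr(X_a, X_b))/2.
  This penalizes spatially rough loadings and encodes the biological
  expectation that functional networks are locally coherent on the
  cortical sheet. The weight is beta * T / (K * n_m), n_m being the
  mean neighbour count (6 on an icosphere).
* **Group consensus / sparsity**: the L2,1-ratio term over the stacked
  subject loadings of each network, weighted by alpha * n * T / K. For
  several subjects it pulls homologous networks toward a shared
  support; for a single matrix it reduces to the per-column L1/L2
  ratio, a scale-invariant sparsity measure.

Defaults are alpha = 1, beta = 10, the validated setting for this
family of decompositions.

The solver uses multiplicative updates (the standard
nonnegativity-preserving scheme for graph-regularized NMF), with the
consensus term entering through its split subgradient. Multiplicative
updates are not guaranteed monotone for the ratio term, so every
iteration is guarded by a step-halving safeguard: a candidate update
that would increase the objective is blended back toward the previous
iterate until the objective is non-increasing, and the solver stops if
no decrease is possible. The recorded objective trace is therefore
non-increasing by construction, and the tests assert it. Convergence
uses a relative objective change below `tol` (default 1e-6) or
`max_iter` (default 300). The max-norm constraint on each network
(column max of V equals 1) is applied at convergence, with the inverse
scale folded into U so U V' is unchanged.

**Consensus at the group stage.** The pooled group decomposition also
includes the (n = 1) sparsity form of the consensus term. The ratio is
scale-invariant but *shape*-dependent, and dropping it lets the pooled
loadings drift toward diffuse, overlapping solutions on range-normalized
data; with it, group networks stay parts-based and the downstream atlas
and personalization recover the planted topography. This is a
deliberate design choice of this package: alpha is a sparsity control
at every stage, not only in the joint multi-subject model.

# Atlas construction and personalization

Group decompositions are repeated on random subject subsets
(desk-scale defaults: 20 subjects per subset, 10 replicates; the
study-scale convention is 100 and 50) and the stacked networks are
fused: pairwise network distance d = 1 - Pearson correlation of
loading vectors, similarity exp(-d^2 / sigma^2) with sigma the median
distance, normalized-cut spectral clustering (symmetric normalized
Laplacian, seeded k-means on the leading K eigenvectors) into K
clusters, and per cluster the member with maximal summed within-cluster
similarity (self-similarity excluded) becomes the representative.
Representatives are ordered by stack position for determinism. An
empty cluster triggers up to five re-runs with fresh k-means seeds
before erroring.

Personalization runs the joint model for one subject initialized at
the fused atlas. Initialization, not a hard constraint, preserves
network correspondence; the tests verify that the best-match ordering
between a personalized solution and the atlas is the identity
assignment and that data generated exactly from the atlas are
recovered with matched correlations above 0.95. Hard partitions label
each vertex by its maximal loading, ties toward the lower network
index, all-zero rows unassigned.

# Coupling, hierarchy and variability

Between-network coupling is plain Pearson correlation of timeseries,
averaged raw (no Fisher transform): per network pair the mean over all
cross-network vertex pairs; per network the mean of its off-diagonal
row; per vertex the mean correlation to all out-of-network vertices.
Subjects' own personalized partitions define membership for coupling,
while hierarchy summaries use the group-consensus partition — mirroring
how individual statistics and group anatomy are kept separate.

The functional hierarchy is an input map (unimodal to transmodal,
rescaled to [0, 1]). A network's hierarchy value is the mean map value
over its group-partition vertices; an edge's hierarchical distance is
the absolute difference of its two networks' values; the mean pairwise
3D Euclidean distance between member vertices serves as the geometric
sensitivity covariate.

Topographic variability is the median absolute deviation (MAD, no
consistency constant) of loadings across subjects, per vertex and
network, averaged over the K networks, optionally z-scored within a
scale. Its spatial alignment with the hierarchy is tested with a spin
test: the mesh is an icosphere, so random 3D rotations with
nearest-vertex resampling are exact spherical permutations that
preserve spatial autocorrelation. p-values use the add-one rule and
are two-sided.

# Inferential models

Per coupling unit, age effects come from `mgcv` GAMs
`y ~ s(age) + sex + motion` with thin-plate penalized splines and REML
smoothness selection; EF effects add `s(EF)` while covarying
`s(age)`. The effect size is the change in adjusted R-squared between
the full and nested model, signed by the age (or EF) coefficient of
the equivalent linear model; significance is the ANOVA F comparison,
FDR-corrected (Benjamini–Hochberg, q = 0.05) within each analysis
family. Windows of credible change are contiguous grid runs where the
pointwise 95% band of the smooth's first derivative (finite
differences of the linear-predictor matrix, coefficient draws from the
fit's posterior) excludes zero.

Second-order structure is modeled by OLS of unit effects on network
hierarchy (optionally with a squared term for the EF analysis), on
hierarchical distance for edges (with a partial correlation
controlling Euclidean distance), and by a tensor-product surface over
the two networks' hierarchy positions for visualization with a
bootstrap of the linear interaction term for inference. All bootstrap
CIs resample the analysis units with replacement (percentile, 1000
draws by default). Resampling *subjects* and recomputing the per-scale
statistic — the expensive variant — is available through the
`recompute` hook of `scaleTrend()`.

GEEs across scales use fixed, unpenalized spline bases (mgcv
`smoothCon`, k = 4) for scale and age, an exchangeable working
correlation estimated by moments, and a robust sandwich covariance;
scale effects and scale-by-age or scale-by-EF product-basis blocks are
tested with joint Wald chi-square statistics. No GEE solver dependency
is used; the estimating equations are iterated directly, which the
tests calibrate against planted intraclass correlations and null
rejection rates.

# Prediction

EF is predicted from the concatenated multi-scale edge couplings by
ridge regression with nested split-thirds tuning: per repeat,
coefficients for each penalty in a 20-point log-spaced grid are fit on
the first third (closed-form SVD path), the penalty minimizing MSE on
the second third is chosen, and the unseen final third is predicted.
Age and motion are regressed out of EF using a projection estimated on
the fitting third only, and feature standardization likewise uses
fitting-third statistics, so the evaluation third never influences
fitting or tuning — a property enforced by a leakage canary test.
Final predictions average over the repeats in which a subject fell in
the evaluation third; significance compares the observed correlation
against full re-runs on permuted EF (one-sided, add-one rule).

# The synthetic generator

The generator plants known structure at every level so that each
stage's recovery can be measured:

* **Mesh**: an icosphere (10 * 4^n + 2 vertices; default n = 2, 162
  vertices). Icospheres make spin-test rotations exact and give a
  nearly regular neighbour structure (n_m about 6, as for a cortical
  surface mesh).
* **Hierarchy map**: the z-coordinate plus smoothed noise, rescaled to
  [0, 1] — a smooth axis from one pole (unimodal) to the other
  (transmodal).
* **Networks**: recursive bipartition of the mesh (always splitting
  the largest cluster at its two farthest members, with medoid
  recentering), giving spatially contiguous, *nested* parcels: the
  same split tree generates every scale, so each fine network sits
  inside one K = 2 half. Loadings are mildly plateau-shaped distance
  kernels, `exp(-(d^2/(2 r^2 * 0.8))^1.5)`, max-normalized. The
  plateau shape matters: per-vertex range normalization of the
  timeseries (the preprocessing the factorization requires) erases
  absolute amplitude, so a peaked kernel profile would be
  unidentifiable in principle; a near-flat membership profile with a
  fast border falloff is both identifiable and keeps off-network tails
  small enough that measured vertex-level coupling tracks the planted
  network-level coupling (regression slope within [0.9, 1.1] at
  T = 555).
* **Topography**: per-subject multiplicative loading perturbations
  with standard deviation `topo_sd * hierarchy`, so individual
  variability grows toward transmodal cortex.
* **Coupling**: per scale, edge targets
  rho = rho0 - a * hdist + b_e * (age - age0) + dev, with
  b_e = age_slope * (1 - 2 * pairmean - 1.5 * hdist): positive for
  hierarchically close unimodal pairs, negative for distant and
  transmodal pairs, so network-level age effects decline along the
  hierarchy and edge-level effects anti-correlate with hierarchical
  distance by construction. `dev` are stable per-subject edge
  deviations (sd 0.12, the order of between-subject FC variability).
  Matrices are repaired to valid correlation matrices by eigenvalue
  clipping and unit-diagonal renormalization.
* **Timeseries**: K Gaussian network courses with the target
  correlation (Cholesky), shifted positive, mixed through the subject
  loadings, plus vertex noise (sd 0.05).
* **EF**: a weighted sum of the *age-detrended* couplings (the subject
  deviations) plus an explicit age trend and noise. Weights follow a
  hierarchy-extremeness pattern — negative for edges joining networks
  near either end of the realized hierarchy range, mildly positive for
  mid-hierarchy edges, zero for weakly patterned edges — so greater
  segregation of both sensorimotor-like and default-mode-like networks
  predicts better EF, and the network-level EF effect is quadratic in
  hierarchy position. Planting EF on age-detrended couplings keeps the
  EF-age relation exactly at its configured slope; planting it on raw
  couplings would let the many planted age slopes leak into EF and
  confound the age-controlled models.

Two entry points exist. `simulateStudy()` produces full BOLD-like
timeseries (courses generated from the `gen_scale` networks, default
K = 4) for the NMF / atlas / coupling-measurement path.
`simulateCouplingStudy()` skips timeseries and returns per-scale
couplings equal to the planted targets plus sampling noise of sd
1.5/sqrt(T) — the stochastic error of an averaged correlation at T
timepoints — for the inferential and predictive stages, where many
scales and subjects are needed and the NMF path would dominate the
runtime without adding information about the statistics under test.

**What the generator does not emulate**: hemodynamics, realistic noise
spectra (1/f, physiological), motion artifacts, spatially varying SNR,
inter-subject misregistration, or non-stationary coupling. Passing
tests therefore demonstrate that the *algorithms* recover planted
structure of realistic size and layout — not that real cortical data
meet the model's assumptions.

# Problem sizes and defaults

Desk-scale study conditions, chosen once as a realistic miniature of a
developmental cohort and used by the tests and the acceptance script:

* mesh: 162 vertices; cohort: 40 subjects for the timeseries path;
  T = 555 timepoints (the length of a concatenated multi-run session);
  ages uniform on 8–23; motion lognormal around 0.08 mm.
* bootstrap atlases: 10 replicates of 20-subject subsets (study-scale:
  50 of 100); NMF max_iter 300 (bootstrap) / 100 (personalization).
* inferential recovery runs: 200 subjects, scales 2–10 at the network
  level and 2–8 at the edge level (54 network and 119 edge units),
  1000-draw bootstraps, 200 permutations — unit counts at which the
  planted second-order relations are reliably detected, standing in
  for the study-scale sweep of 29 scales and several hundred units.

At desk scale the cross-subject MAD of *fitted* loadings is dominated
by NMF estimation noise (each subject's loadings carry independent
optimization error of roughly the same size as the planted
topographic variability), so the variability-hierarchy alignment is
strong on the generator's subject loadings but near zero on the fitted
ones; both are reported by the reproduction script. Recovering the
alignment from fitted loadings requires the study-scale vertex count
and cohort, where estimation error averages down relative to the
planted gradient.

# Known limitations

* Multiplicative updates converge slowly near boundary solutions;
  exact planted-factor recovery needs thousands of iterations (the
  tests use small matrices there). The safeguard can stall early at a
  local objective plateau.
* The GEE Wald test uses the plain sandwich estimator; with few
  clusters it is mildly liberal. Calibration is verified at 80
  clusters.
* The spin test resamples by nearest vertex; on very coarse meshes
  repeated assignment slightly discretizes the null.
* Atlas fusion is deterministic given its seed, but spectral k-means
  can legitimately relabel clusters across seeds; all comparisons go
  through best-match assignment.
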