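#' @import methods
NULL

#' Triangulated spherical surface mesh
#'
#' An icosphere standing in for a spherical cortical surface projection
#' (e.g. a FreeSurfer sphere). Vertices lie on the unit sphere; the
#' neighbour structure comes from triangle edges and drives both the
#' locality (graph-Laplacian) regularization of the NMF and the planted
#' spatial contiguity of synthetic networks. Rotations of the sphere are
#' exact, which keeps the spin test free of projection artefacts.
#'
#' @slot coords numeric matrix, S x 3, unit-norm vertex coordinates.
#' @slot faces integer matrix, F x 3, triangle vertex indices.
#' @slot neighbors list of length S; integer indices of the vertices
#'   sharing an edge with each vertex.
#'
#' @seealso [buildSphereMesh()]
#' @export
setClass("SurfaceMesh",
  representation(
    coords = "matrix",
    faces = "matrix",
    neighbors = "list"
  )
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  S <- nrow(object@coords)
  if (ncol(object@coords) != 3L) {
    msg <- c(msg, "coords must have 3 columns")
  }
  nrm <- sqrt(rowSums(object@coords^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    msg <- c(msg, "all vertex coordinates must be unit-norm (tol 1e-9)")
  }
  if (length(object@neighbors) != S) {
    msg <- c(msg, "neighbors must have one entry per vertex")
  }
  deg <- lengths(object@neighbors)
  if (any(deg < 3L)) {
    msg <- c(msg, "every vertex must have at least 3 neighbors")
  }
  # symmetry of the neighbour relation
  for (v in seq_len(min(S, length(object@neighbors)))) {
    for (w in object@neighbors[[v]]) {
      if (!(v %in% object@neighbors[[w]])) {
        msg <- c(msg, sprintf("adjacency not symmetric at (%d,%d)", v, w))
        break
      }
    }
    if (length(msg) > 0 && grepl("symmetric", msg[length(msg)])) break
  }
  if (length(msg)) msg else TRUE
})

#' Fused group-consensus network atlas at one scale
#'
#' Holds the representative group networks selected after spectral-cluster
#' fusion of bootstrap NMF decompositions, used to initialize every
#' subject's personalized solution so networks correspond across subjects.
#'
#' @slot loadings numeric matrix, S x K, nonnegative, each column
#'   max-normalized to 1.
#' @slot scale integer, the number of networks K.
#' @slot provenance integer vector of length K; index of the stacked
#'   bootstrap network each representative was taken from.
#'
#' @seealso [fuseAtlases()], [personalizeNetworks()]
#' @export
setClass("GroupAtlas",
  representation(
    loadings = "matrix",
    scale = "integer",
    provenance = "integer"
  )
)

setValidity("GroupAtlas", function(object) {
  msg <- character()
  K <- object@scale
  if (ncol(object@loadings) != K) {
    msg <- c(msg, "loadings must have K columns")
  }
  if (any(object@loadings < 0)) {
    msg <- c(msg, "loadings must be nonnegative")
  }
  cmax <- apply(object@loadings, 2L, max)
  if (any(abs(cmax - 1) > 1e-8)) {
    msg <- c(msg, "each network column must have max loading 1")
  }
  if (length(object@provenance) != K) {
    msg <- c(msg, "provenance must have one entry per network")
  }
  if (length(msg)) msg else TRUE
})

#' Between-network coupling of one subject at one scale
#'
#' Coupling is plain Pearson correlation of BOLD timeseries summarized at
#' three levels: the K x K edge matrix of mean vertex-by-vertex
#' correlations between network pairs, the per-network mean coupling to
#' all other networks, and the per-vertex mean correlation to all
#' out-of-network vertices.
#'
#' @slot subjectId character scalar.
#' @slot scale integer, number of networks K.
#' @slot edgeMatrix K x K symmetric matrix; off-diagonal cells are
#'   between-network coupling, the diagonal stores the within-network mean
#'   pairwise correlation (informational). Cells for empty networks are NA.
#' @slot networkVector length-K mean off-diagonal coupling per network.
#' @slot vertexVector length-S per-vertex out-of-network coupling.
#'
#' @seealso [computeCoupling()]
#' @export
setClass("CouplingSet",
  representation(
    subjectId = "character",
    scale = "integer",
    edgeMatrix = "matrix",
    networkVector = "numeric",
    vertexVector = "numeric"
  )
)

setValidity("CouplingSet", function(object) {
  msg <- character()
  K <- object@scale
  E <- object@edgeMatrix
  if (!all(dim(E) == c(K, K))) {
    msg <- c(msg, "edgeMatrix must be K x K")
  }
  if (any(abs(E) > 1 + 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "coupling values must lie in [-1, 1]")
  }
  if (any(abs(E - t(E)) > 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "edgeMatrix must be symmetric")
  }
  if (length(object@networkVector) != K) {
    msg <- c(msg, "networkVector must have length K")
  }
  off <- E
  diag(off) <- NA
  nv <- rowMeans(off, na.rm = TRUE)
  nv[is.nan(nv)] <- NA_real_
  if (!isTRUE(all.equal(nv, object@networkVector, tolerance = 1e-8,
                        check.attributes = FALSE))) {
    msg <- c(msg, "networkVector inconsistent with edgeMatrix row means")
  }
  if (length(msg)) msg else TRUE
})
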