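#' @rdname SurfaceMesh-class
#' @param object,x a \code{SurfaceMesh}, \code{GroupAtlas} or
#'   \code{CouplingSet} object.
#' @export
setGeneric("vertexCoords", function(x) standardGeneric("vertexCoords"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("neighborLists", function(x) standardGeneric("neighborLists"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname GroupAtlas-class
#' @export
setGeneric("atlasLoadings", function(x) standardGeneric("atlasLoadings"))

#' @rdname GroupAtlas-class
#' @export
setGeneric("networkScale", function(x) standardGeneric("networkScale"))

#' @rdname CouplingSet-class
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname CouplingSet-class
#' @export
setGeneric("networkCouplingOf", function(x) standardGeneric("networkCouplingOf"))

#' @rdname CouplingSet-class
#' @export
setGeneric("vertexCouplingOf", function(x) standardGeneric("vertexCouplingOf"))

setMethod("vertexCoords", "SurfaceMesh", function(x) x@coords)
setMethod("neighborLists", "SurfaceMesh", function(x) x@neighbors)
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@coords))
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

setMethod("atlasLoadings", "GroupAtlas", function(x) x@loadings)
setMethod("networkScale", "GroupAtlas", function(x) x@scale)

setMethod("edgeMatrix", "CouplingSet", function(x) x@edgeMatrix)
setMethod("networkCouplingOf", "CouplingSet", function(x) x@networkVector)
setMethod("vertexCouplingOf", "CouplingSet", function(x) x@vertexVector)

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh with", nrow(object@coords), "vertices,",
      nrow(object@faces), "faces\n")
  deg <- lengths(object@neighbors)
  cat("  vertex degree:", min(deg), "-", max(deg), "\n")
})

setMethod("show", "GroupAtlas", function(object) {
  cat("GroupAtlas at scale K =", object@scale, "on",
      nrow(object@loadings), "vertices\n")
})

setMethod("show", "CouplingSet", function(object) {
  cat("CouplingSet for subject", object@subjectId,
      "at scale K =", object@scale, "\n")
  cat("  mean between-network coupling:",
      signif(mean(object@networkVector, na.rm = TRUE), 4), "\n")
})
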