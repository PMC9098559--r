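#' Build an icosphere surface mesh
#'
#' Constructs a triangulated sphere by repeated 4-fold subdivision of a
#' regular icosahedron, with every new vertex projected back onto the
#' unit sphere. The result is a proxy for a spherical cortical-surface
#' projection: vertex count is \eqn{10 \cdot 4^n + 2} for \code{n}
#' subdivisions (12, 42, 162, 642, ...), and the triangle edges define
#' the neighbour structure used for spatial regularization.
#'
#' @param subdivisions non-negative integer; number of subdivision passes.
#' @return a [SurfaceMesh-class] object.
#' @examples
#' mesh <- buildSphereMesh(1)
#' nVertices(mesh)  # 42
#' @export
buildSphereMesh <- function(subdivisions = 2L) {
  stopifnot(length(subdivisions) == 1L, subdivisions >= 0)
  subdivisions <- as.integer(subdivisions)

  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )

  for (iter in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    vlist <- list(verts)
    nv <- nrow(verts)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b), sep = "_")
      idx <- midpoint_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (vlist[[1L]][a, ] + vlist[[1L]][b, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[1L]] <<- rbind(vlist[[1L]], m)
      nv <<- nv + 1L
      midpoint_cache[[key]] <- nv
      nv
    }
    new_faces <- matrix(0L, nrow = 4L * nrow(faces), ncol = 3L)
    for (f in seq_len(nrow(faces))) {
      v1 <- faces[f, 1L]; v2 <- faces[f, 2L]; v3 <- faces[f, 3L]
      a <- midpoint(v1, v2); b <- midpoint(v2, v3); c3 <- midpoint(v3, v1)
      new_faces[(f - 1L) * 4L + 1L, ] <- c(v1, a, c3)
      new_faces[(f - 1L) * 4L + 2L, ] <- c(v2, b, a)
      new_faces[(f - 1L) * 4L + 3L, ] <- c(v3, c3, b)
      new_faces[(f - 1L) * 4L + 4L, ] <- c(a, b, c3)
    }
    verts <- vlist[[1L]]
    faces <- new_faces
  }

  dimnames(verts) <- NULL
  new("SurfaceMesh",
      coords = verts,
      faces = faces,
      neighbors = faces_to_neighbors(faces, nrow(verts)))
}

# Neighbour lists from triangle edges (sorted, unique).
faces_to_neighbors <- function(faces, n_vertices) {
  edges <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  edges <- rbind(edges, edges[, c(2L, 1L)])
  nb <- split(edges[, 2L], factor(edges[, 1L], levels = seq_len(n_vertices)))
  lapply(nb, function(v) sort(unique(as.integer(v))))
}

# Mean vertex degree, the n_m entering the locality weight.
mean_degree <- function(mesh) {
  mean(lengths(neighborLists(mesh)))
}

#' Read or write a mesh in OFF format
#'
#' Plain-text Object File Format round trip: `writeMeshOFF` stores vertex
#' coordinates and triangle faces; `readMeshOFF` rebuilds the
#' [SurfaceMesh-class] including neighbour lists (and validates it).
#'
#' @param mesh a `SurfaceMesh`.
#' @param path file path.
#' @return `readMeshOFF` returns a `SurfaceMesh`; `writeMeshOFF` returns
#'   `path` invisibly.
#' @export
writeMeshOFF <- function(mesh, path) {
  co <- vertexCoords(mesh)
  fa <- meshFaces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(co), nrow(fa)), con)
  writeLines(sprintf("%.17g %.17g %.17g", co[, 1L], co[, 2L], co[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", fa[, 1L] - 1L, fa[, 2L] - 1L, fa[, 3L] - 1L),
             con)
  invisible(path)
}

#' @rdname writeMeshOFF
#' @export
readMeshOFF <- function(path) {
  lines <- readLines(path)
  if (!identical(trimws(lines[1L]), "OFF")) {
    stop("not an OFF file: missing header")
  }
  counts <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  co <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"))),
               ncol = 3L, byrow = TRUE)
  fl <- strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+")
  fa <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  new("SurfaceMesh", coords = co, faces = fa,
      neighbors = faces_to_neighbors(fa, nv))
}
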