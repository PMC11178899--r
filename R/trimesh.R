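#' Indexed triangle mesh
#'
#' The central container: an indexed triangle surface with vertex positions
#' in millimetres. Faces are 1-based integer triples into the position
#' matrix. Vertex normals and the edge graph are derived on demand by
#' [vertex_normals()] and [edge_graph()].
#'
#' @param positions numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param provenance optional list describing the source (path, dialect).
#' @return An object of class `trimesh`: a list with elements `positions`,
#'   `faces` and `provenance`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'              matrix(c(1L, 2L, 3L), 1))
#' n_vertices(m)
#' @export
trimesh <- function(positions, faces, provenance = NULL) {
  positions <- as.matrix(positions)
  # drop any stray attributes (names, computation metadata)
  positions <- matrix(as.double(positions), nrow(positions), ncol(positions))
  faces <- as.matrix(faces)
  faces <- matrix(as.integer(faces), nrow(faces), ncol(faces))
  if (ncol(positions) != 3L) stopf("positions must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L)
    stopf("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  if (!all(is.finite(positions))) stopf("non-finite vertex coordinate")
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(positions))
      stopf("face index out of range [1, %d]", nrow(positions))
  }
  dimnames(positions) <- NULL
  dimnames(faces) <- NULL
  structure(list(positions = positions, faces = faces,
                 provenance = provenance),
            class = "trimesh")
}

#' @rdname trimesh
#' @param x,mesh a `trimesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$positions)

#' @rdname trimesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname trimesh
#' @param ... ignored.
#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$positions, 2, range)
  cat(sprintf("trimesh: %d vertices, %d faces\n", n_vertices(x), n_faces(x)))
  cat(sprintf("bounding box (mm): [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Mesh centroid
#'
#' Mean of the vertex positions (vertex centroid, not an area-weighted
#' surface centroid). Used as rotation and mirror center by the
#' augmentation operations.
#'
#' @param mesh a `trimesh`.
#' @return numeric length-3 vector, mm.
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$positions)

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed surface with outward-oriented (counter-clockwise) winding.
#' Used by tests to verify that mirroring restores orientation.
#'
#' @param mesh a `trimesh`.
#' @return signed volume in mm^3.
#' @export
mesh_signed_volume <- function(mesh) {
  p <- mesh$positions
  a <- p[mesh$faces[, 1], , drop = FALSE]
  b <- p[mesh$faces[, 2], , drop = FALSE]
  c <- p[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cr)) / 6
}
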