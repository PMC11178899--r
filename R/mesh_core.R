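# Mesh connectivity, normals, graph-approximated geodesics, vertex point
# cover, and scattered interpolation — the substrate for gradient maps.

face_normals_raw <- function(mesh) {
  p <- mesh$positions
  f <- mesh$faces
  a <- p[f[, 1], , drop = FALSE]
  u <- p[f[, 2], , drop = FALSE] - a
  v <- p[f[, 3], , drop = FALSE] - a
  # cross product; magnitude = 2 * face area, direction follows winding
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-vertex unit normals
#'
#' Area-weighted average of incident face normals, normalized to unit
#' length. Orientation follows face winding (counter-clockwise seen from
#' outside gives outward normals). Degenerate zero-area faces contribute
#' zero weight. Vertices with no incident face, or whose incident faces are
#' all degenerate, get a zero normal and are reported via the
#' `"zero_normal"` attribute.
#'
#' @param mesh a [trimesh].
#' @return n x 3 matrix of unit normals, with attribute `zero_normal`
#'   (integer indices of vertices without a usable normal).
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals_raw(mesh)   # area-weighted by construction
  idx <- as.vector(mesh$faces)
  acc <- rowsum(fn[rep(seq_len(n_faces(mesh)), 3L), , drop = FALSE],
                group = idx, reorder = FALSE)
  out <- matrix(0, n_vertices(mesh), 3)
  out[as.integer(rownames(acc)), ] <- acc
  nn <- row_norms(out)
  zero <- which(nn < 1e-12)
  out <- normalize_rows(out)
  attr(out, "zero_normal") <- zero
  out
}

face_edge_keys <- function(faces) {
  e1 <- faces[, c(1, 2), drop = FALSE]
  e2 <- faces[, c(2, 3), drop = FALSE]
  e3 <- faces[, c(3, 1), drop = FALSE]
  e <- rbind(e1, e2, e3)
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Cross-edge face adjacency
#'
#' Faces adjacent across a shared edge. On a closed manifold every face has
#' exactly 3 neighbors; boundary faces have fewer. An edge shared by more
#' than two faces is a non-manifold defect and raises an error naming the
#' edge.
#'
#' @param mesh a [trimesh].
#' @return list of length `n_faces(mesh)`; element i is an integer vector
#'   of face indices sharing an edge with face i.
#' @export
face_adjacency <- function(mesh) {
  nf <- n_faces(mesh)
  keys <- face_edge_keys(mesh$faces)
  fid <- rep(seq_len(nf), 3L)
  by_edge <- split(fid, keys)
  counts <- lengths(by_edge)
  if (any(counts > 2L)) {
    bad <- names(by_edge)[which(counts > 2L)[1]]
    stopf("non-manifold edge (%s) shared by %d faces",
          gsub(" ", "-", bad), max(counts))
  }
  adj <- vector("list", nf)
  for (fp in by_edge[counts == 2L]) {
    adj[[fp[1]]] <- c(adj[[fp[1]]], fp[2])
    adj[[fp[2]]] <- c(adj[[fp[2]]], fp[1])
  }
  lapply(adj, function(x) sort(unique(x %||% integer(0))))
}

#' Euclidean vertex neighborhood with a K cap
#'
#' All vertices strictly within `radius` of the center vertex; if more than
#' `k_max` qualify, the `k_max` nearest are kept (distance ties broken by
#' lower vertex index). The center itself is included at distance 0.
#'
#' @param mesh a [trimesh].
#' @param center vertex index (1-based).
#' @param radius search radius in mm, > 0.
#' @param k_max maximum number of vertices returned, >= 1.
#' @return integer vector of vertex indices.
#' @export
vertex_neighborhood <- function(mesh, center, radius, k_max = Inf) {
  nv <- n_vertices(mesh)
  if (length(center) != 1L || is.na(center) || center < 1L || center > nv)
    stopf("invalid center vertex index: %s", center)
  if (radius <= 0) stopf("radius must be > 0")
  if (k_max < 1) stopf("k_max must be >= 1")
  d <- row_norms(mesh$positions -
                   rep(mesh$positions[center, ], each = nv))
  inside <- which(d < radius)
  if (length(inside) > k_max) {
    inside <- inside[order(d[inside], inside)][seq_len(k_max)]
  }
  sort(inside)
}

#' Edge graph of a mesh
#'
#' Undirected vertex adjacency from face edges, weighted by Euclidean edge
#' length in mm. This graph is the basis of all geodesic approximations.
#'
#' @param mesh a [trimesh].
#' @return an [igraph::graph] with `n_vertices(mesh)` vertices and a
#'   `weight` edge attribute.
#' @export
edge_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- row_norms(mesh$positions[e[, 1], , drop = FALSE] -
                   mesh$positions[e[, 2], , drop = FALSE])
  g <- igraph::make_empty_graph(n = n_vertices(mesh), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(e)))
  igraph::E(g)$weight <- w
  g
}

#' Graph-approximated geodesic distances from one vertex
#'
#' Shortest-path distances along the edge graph with Euclidean edge
#' weights (Dijkstra), truncated at `cutoff`. A graph path lies on the
#' surface, so these distances upper-bound straight-line distance and
#' approximate true surface geodesics from above.
#'
#' @param mesh a [trimesh].
#' @param source vertex index.
#' @param cutoff truncation distance in mm, > 0.
#' @param graph optional precomputed [edge_graph()].
#' @return named numeric vector mapping vertex index to distance, only for
#'   vertices within `cutoff` (the source maps to 0). Disconnected or
#'   too-distant vertices are absent.
#' @export
graph_geodesic_distances <- function(mesh, source, cutoff, graph = NULL) {
  if (cutoff <= 0) stopf("cutoff must be > 0")
  g <- graph %||% edge_graph(mesh)
  d <- as.vector(igraph::distances(g, v = source, algorithm = "dijkstra"))
  keep <- which(is.finite(d) & d <= cutoff)
  stats::setNames(d[keep], keep)
}

#' Greedy geodesic vertex point cover
#'
#' A vertex point cover C(M; rho) is a vertex subset such that every mesh
#' vertex lies within graph-geodesic distance `rho` of some cover vertex.
#' It is built greedily in breadth-first order from a start vertex: a
#' vertex joins the cover iff no current cover vertex is within `rho` of
#' it. The result is deterministic, covers every (candidate) vertex, and
#' is maximally separated: no two cover vertices are within `rho` of each
#' other. Disconnected meshes are processed per component, starting each
#' component at its lowest candidate index.
#'
#' @param mesh a [trimesh].
#' @param rho cover radius in mm, > 0.
#' @param mode `"weighted"` (default) uses Euclidean edge lengths as graph
#'   weights — the better geodesic proxy; `"hop"` counts edges, in which
#'   case `rho` is a hop count.
#' @param start start vertex of the breadth-first traversal (default 1).
#' @param candidates optional vertex subset: only these vertices are
#'   required to be covered and eligible as cover points (used to mask a
#'   region of interest).
#' @return object of class `point_cover`: list with `cover_indices`
#'   (integer), `radius_rho`, `mode`.
#' @export
build_point_cover <- function(mesh, rho, mode = c("weighted", "hop"),
                              start = 1L, candidates = NULL) {
  if (rho <= 0) stopf("rho must be > 0")
  mode <- match.arg(mode)
  g <- edge_graph(mesh)
  w <- if (mode == "weighted") igraph::E(g)$weight else rep(1, igraph::ecount(g))
  igraph::E(g)$weight <- w
  nv <- n_vertices(mesh)
  cand <- sort(unique(as.integer(candidates %||% seq_len(nv))))
  if (length(cand) == 0L) stopf("empty candidate set")

  comp <- igraph::components(g)$membership
  dist_to_cover <- rep(Inf, nv)
  cover <- integer(0)
  for (cm in unique(comp[cand])) {
    members <- intersect(which(comp == cm), cand)
    root <- if (start %in% members) start else min(members)
    bfs_order <- as.integer(igraph::bfs(g, root = root,
                                        unreachable = FALSE)$order)
    bfs_order <- bfs_order[!is.na(bfs_order)]
    bfs_order <- bfs_order[bfs_order %in% members]
    for (v in bfs_order) {
      if (dist_to_cover[v] >= rho) {
        cover <- c(cover, v)
        dv <- as.vector(igraph::distances(g, v = v))
        dist_to_cover <- pmin(dist_to_cover, dv)
      }
    }
  }
  structure(list(cover_indices = cover, radius_rho = rho, mode = mode),
            class = "point_cover")
}

#' @export
print.point_cover <- function(x, ...) {
  cat(sprintf("point_cover: %d points, rho = %g (%s graph distance)\n",
              length(x$cover_indices), x$radius_rho, x$mode))
  invisible(x)
}

#' Interpolate values from a point cover to all vertices
#'
#' Inverse-graph-distance weighting (exponent 1) over the `k` nearest
#' cover points by graph distance. Exact at cover vertices; everywhere the
#' output lies within the range of the cover values. Distance ties are
#' broken by lower vertex index.
#'
#' @param mesh a [trimesh].
#' @param cover a `point_cover` from [build_point_cover()].
#' @param cover_values numeric vector named by cover vertex index, or in
#'   the order of `cover$cover_indices` if unnamed.
#' @param k number of nearest cover points to blend (default 3).
#' @param graph optional precomputed [edge_graph()].
#' @return numeric vector of length `n_vertices(mesh)`.
#' @export
interpolate_cover_values <- function(mesh, cover, cover_values, k = 3L,
                                     graph = NULL) {
  ci <- cover$cover_indices
  if (length(ci) == 0L) stopf("empty cover")
  if (!is.null(names(cover_values))) {
    if (!setequal(names(cover_values), as.character(ci)))
      stopf("cover_values names must match cover indices exactly")
    vals <- as.numeric(cover_values[as.character(ci)])
  } else {
    if (length(cover_values) != length(ci))
      stopf("need %d cover values, got %d", length(ci), length(cover_values))
    vals <- as.numeric(cover_values)
  }
  g <- graph %||% edge_graph(mesh)
  if (cover$mode == "hop") igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  D <- igraph::distances(g, v = ci)   # |cover| x nv
  nv <- n_vertices(mesh)
  k <- min(k, length(ci))
  out <- numeric(nv)
  for (v in seq_len(nv)) {
    d <- D[, v]
    ord <- order(d, ci)[seq_len(k)]
    dn <- d[ord]
    if (dn[1] == 0) {
      out[v] <- vals[ord[1]]
    } else if (all(is.infinite(dn))) {
      out[v] <- NA_real_   # unreachable from the cover (other component)
    } else {
      wgt <- 1 / dn[is.finite(dn)]
      out[v] <- sum(wgt * vals[ord[is.finite(dn)]]) / sum(wgt)
    }
  }
  out
}
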