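# The core method: local normal-direction deformation of a mesh, score
# differencing against the undeformed mesh, sparse evaluation on a point
# cover, and interpolation to a per-vertex gradient field.

#' Linear radial falloff
#'
#' The weight `sigma(r; R) = max(0, (R - r) / R)` that controls how strongly
#' a perturbation centered at a vertex drags vertices at distance `r`:
#' 1 at the center, linearly decaying to 0 at the range `R`, and 0 beyond.
#' The linear profile yields natural-looking, surgically plausible bumps.
#'
#' @param r distance(s) in mm, >= 0.
#' @param range_R falloff range in mm, > 0.
#' @return weights in \[0, 1\], same length as `r`.
#' @export
sigma_falloff <- function(r, range_R) {
  if (range_R <= 0) stopf("range_R must be > 0")
  if (any(r < 0)) stopf("negative distance")
  pmax(0, (range_R - r) / range_R)
}

#' Deformation specification
#'
#' @param delta signed displacement in mm; positive makes a bump, negative
#'   a dent.
#' @param range_R falloff range in mm (> 0): vertices farther than this from
#'   the center are not moved.
#' @param distance_mode how the distance inside the falloff is measured:
#'   `"euclidean"` (straight-line, the default) or `"geodesic"` (graph
#'   distance along the surface, which avoids dragging spatially close but
#'   anatomically distant surfaces such as the inner skull table).
#' @return object of class `deformation_spec`.
#' @export
deformation_spec <- function(delta = 2, range_R = 20,
                             distance_mode = c("euclidean", "geodesic")) {
  if (!is.finite(delta)) stopf("delta must be finite")
  if (range_R <= 0) stopf("range_R must be > 0")
  structure(list(delta = delta, range_R = range_R,
                 distance_mode = match.arg(distance_mode)),
            class = "deformation_spec")
}

#' Scoring function wrapper
#'
#' A scoring function maps a mesh to a class belief in \[0, 1\]. By package
#' convention a score of 1 means "female-like", so a positive gradient at a
#' vertex reads "pushing this area outward makes the shape more
#' female-like".
#'
#' @param fn function taking a [trimesh] and returning a single number in
#'   \[0, 1\]; must be deterministic for a fixed mesh.
#' @param name short label used in outputs.
#' @return object of class `scoring_function` (callable).
#' @export
scoring_function <- function(fn, name = "scorer") {
  stopifnot(is.function(fn))
  structure(fn, name = name, class = c("scoring_function", "function"))
}

score_mesh <- function(scorer, mesh) {
  s <- scorer(mesh)
  if (length(s) != 1L || !is.finite(s) || s < 0 || s > 1)
    stopf("scorer '%s' violated its contract: output %s not in [0,1]",
          attr(scorer, "name") %||% "?", paste(format(s), collapse = ","))
  as.numeric(s)
}

#' Locally deform a mesh along vertex normals
#'
#' Every vertex `p` moves by `delta * sigma(dist(p, center); R) * N(p)`,
#' where `N(p)` is the unit normal of the *input* mesh and `dist` is
#' Euclidean or graph-geodesic per `distance_mode`. Vertices beyond `range_R` are
#' untouched; faces are unchanged; the input mesh is not modified.
#'
#' @param mesh a [trimesh].
#' @param center vertex index at the middle of the bump/dent.
#' @param spec a [deformation_spec()].
#' @param normals optional precomputed [vertex_normals()] of `mesh`.
#' @param graph optional precomputed [edge_graph()] (geodesic mode only).
#' @return the deformed [trimesh].
#' @export
deform <- function(mesh, center, spec, normals = NULL, graph = NULL) {
  nv <- n_vertices(mesh)
  if (length(center) != 1L || is.na(center) || center < 1 || center > nv)
    stopf("invalid center vertex index: %s", center)
  normals <- normals %||% vertex_normals(mesh)
  if (spec$distance_mode == "euclidean") {
    d <- row_norms(mesh$positions - rep(mesh$positions[center, ], each = nv))
  } else {
    d <- rep(Inf, nv)
    dd <- graph_geodesic_distances(mesh, center, cutoff = spec$range_R,
                                   graph = graph)
    d[as.integer(names(dd))] <- dd
  }
  w <- numeric(nv)
  inside <- is.finite(d) & d < spec$range_R
  w[inside] <- spec$delta * sigma_falloff(d[inside], spec$range_R)
  trimesh(mesh$positions + w * normals, mesh$faces,
          provenance = mesh$provenance)
}

#' Morphological gradient at one vertex
#'
#' The change in the score caused by the local deformation centered at
#' `center`: `f(T(M)) - f(M)`. The baseline `f(M)` is computed once and can
#' be supplied to avoid repeated evaluation.
#'
#' @param mesh a [trimesh].
#' @param scorer a [scoring_function()].
#' @param center vertex index.
#' @param spec a [deformation_spec()].
#' @param baseline optional cached baseline score `scorer(mesh)`.
#' @param normals,graph optional precomputed normals / edge graph.
#' @return a single number in \[-1, 1\].
#' @export
morphological_gradient_at <- function(mesh, scorer, center, spec,
                                      baseline = NULL, normals = NULL,
                                      graph = NULL) {
  baseline <- baseline %||% score_mesh(scorer, mesh)
  deformed <- deform(mesh, center, spec, normals = normals, graph = graph)
  score_mesh(scorer, deformed) - baseline
}

#' Per-vertex morphological gradient field
#'
#' Dense per-vertex evaluation costs one full scorer call per vertex. The
#' gradient is assumed continuous over the surface, so it is evaluated
#' sparsely: a geodesic point cover of radius `rho` is built, the gradient
#' is computed at each cover vertex, and the cover values are interpolated
#' to all vertices. The total number of scorer invocations is exactly
#' `|cover| + 1` (one baseline call).
#'
#' @param mesh a [trimesh].
#' @param scorer a [scoring_function()].
#' @param spec a [deformation_spec()].
#' @param rho cover radius in mm; smaller rho means a denser cover and a
#'   more faithful but more expensive field. A `rho` below the minimum edge
#'   length degenerates to dense per-vertex evaluation.
#' @param region_mask optional vertex indices restricting evaluation (e.g.
#'   to exclude internal surfaces); vertices outside the mask get 0.
#' @param cover optional precomputed `point_cover` (overrides `rho`).
#' @return object of class `gradient_field`: list with `values` (numeric
#'   per vertex), `spec`, `cover`, `scorer_name`, `baseline`.
#' @export
gradient_field <- function(mesh, scorer, spec = deformation_spec(),
                           rho = spec$range_R / 2, region_mask = NULL,
                           cover = NULL) {
  g <- edge_graph(mesh)
  cover <- cover %||% build_point_cover(mesh, rho, candidates = region_mask)
  normals <- vertex_normals(mesh)
  baseline <- score_mesh(scorer, mesh)
  cv <- vapply(cover$cover_indices, function(v) {
    morphological_gradient_at(mesh, scorer, v, spec, baseline = baseline,
                              normals = normals, graph = g)
  }, numeric(1))
  values <- interpolate_cover_values(mesh, cover, cv, graph = g)
  if (!is.null(region_mask)) {
    outside <- setdiff(seq_len(n_vertices(mesh)), region_mask)
    values[outside] <- 0
  }
  values[is.na(values)] <- 0
  structure(list(values = values, spec = spec, cover = cover,
                 scorer_name = attr(scorer, "name") %||% "scorer",
                 baseline = baseline),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf(
    "gradient_field: %d vertices, %d cover points, baseline %.4f (%s)\n",
    length(x$values), length(x$cover$cover_indices), x$baseline,
    x$scorer_name))
  cat(sprintf("values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# nearest-vertex correspondence: for each row of `to`, index of nearest
# row of `from` (chunked brute force)
nearest_vertex_map <- function(from, to, chunk = 512L) {
  n <- nrow(to)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- to[s:e, , drop = FALSE]
    # squared distances (e-s+1) x nrow(from)
    d2 <- outer(rowSums(block^2), rowSums(from^2), "+") -
      2 * block %*% t(from)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Mirror-symmetrized gradient field
#'
#' Gradient maps of approximately bilaterally symmetric shapes can come out
#' asymmetric purely through scorer idiosyncrasy. Averaging the field with
#' the field of the mirrored mesh (mapped back through nearest-vertex
#' correspondence) suppresses that artifact.
#'
#' @inheritParams gradient_field
#' @param mirror_axis axis of the mirror plane normal: `"x"` (sagittal,
#'   default), `"y"`, or `"z"`; the plane passes through the centroid.
#' @return a `gradient_field` whose `values` are the per-vertex mean of the
#'   original and mirrored-and-mapped-back fields.
#' @export
symmetrized_field <- function(mesh, scorer, spec = deformation_spec(),
                              rho = spec$range_R / 2, mirror_axis = "x") {
  f1 <- gradient_field(mesh, scorer, spec, rho)
  mirrored <- mirror_mesh(mesh, axis = mirror_axis)
  f2 <- gradient_field(mirrored, scorer, spec, rho)
  # map the mirrored field back: original vertex i pairs with the
  # mirrored-mesh vertex occupying (approximately) the same spatial
  # location, i.e. the reflection of i's bilateral partner
  corr <- nearest_vertex_map(mirrored$positions, mesh$positions)
  vals <- (f1$values + f2$values[corr]) / 2
  structure(list(values = vals, spec = spec, cover = f1$cover,
                 scorer_name = f1$scorer_name, baseline = f1$baseline),
            class = "gradient_field")
}
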