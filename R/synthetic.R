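# Synthetic "skull proxy" shapes: closed head-like ellipsoids whose shape
# varies along interpretable dimorphic axes (global size, brow-ridge
# prominence, lower-face width) with additive radial noise. They are not
# anatomically realistic; they reproduce only the statistical structure
# needed to validate the gradient method — a localized masculine feature
# (the brow bump), a regional one (jaw width), a global one (size), and
# overlapping class distributions.

# brow patch direction in (lateral, front, up) mesh coordinates, and its
# angular half-width on the shape (radians)
BROW_DIR <- c(0, 1, 0.7) / sqrt(1 + 0.49)
BROW_THETA <- 0.5

#' Subdivided icosphere
#'
#' Icosahedron refined by `subdivisions` rounds of 4-way triangle midpoint
#' subdivision, vertices projected to the unit sphere. Closed and manifold;
#' 42, 162, 642, 2562 vertices for 1-4 subdivisions.
#'
#' @param subdivisions number of refinement rounds, >= 0.
#' @param radius sphere radius (mm), default 1.
#' @return a [trimesh] with outward (counter-clockwise) winding.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    nf <- nrow(f)
    # midpoint index per undirected edge
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uniq <- !duplicated(key)
    mid_id <- nrow(v) + match(key, key[uniq])
    mids <- (v[e[uniq, 1], , drop = FALSE] + v[e[uniq, 2], , drop = FALSE]) / 2
    v <- rbind(v, normalize_rows(mids))
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  trimesh(v * radius, f)
}

#' Shape parameters of a synthetic skull proxy
#'
#' @param base_radius global size in mm (male skulls are generally larger).
#' @param brow_amplitude height in mm of the outward brow bump on the
#'   upper-front patch (a prominent brow ridge is a masculine trait).
#' @param jaw_width_factor lateral scaling of the lower region (the lower
#'   face is relatively wider in masculine skulls).
#' @param noise_sd standard deviation (mm) of i.i.d. radial Gaussian noise.
#' @param rng_seed integer seed making the noise reproducible.
#' @param label class label: 0 = male, 1 = female.
#' @return object of class `shape_params`.
#' @export
shape_params <- function(base_radius = 92.5, brow_amplitude = 2,
                         jaw_width_factor = 1.03, noise_sd = 0,
                         rng_seed = 1L, label = NA_integer_) {
  if (base_radius <= 0) stopf("base_radius must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(base_radius = base_radius, brow_amplitude = brow_amplitude,
                 jaw_width_factor = jaw_width_factor, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed), label = label),
            class = "shape_params")
}

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

#' Generate a synthetic skull-proxy mesh
#'
#' A subdivided icosphere scaled to a head-like ellipsoid (lateral : front
#' : vertical axes = 0.8 : 1.0 : 0.9 of `base_radius`), with (a) a smooth
#' compact-support outward bump of height `brow_amplitude` centered on the
#' upper-front patch, (b) the lateral coordinates of the lower region
#' scaled by `jaw_width_factor` (smooth ramp, fully applied below the lower
#' third), and (c) i.i.d. Gaussian radial noise. Closed, manifold, and
#' deterministic given `rng_seed`.
#'
#' @param params a [shape_params()].
#' @param subdivisions icosphere refinement rounds (default 3, 642
#'   vertices).
#' @return a [trimesh] with attributes `"brow_patch"` (vertex indices of
#'   the bump support) and `"params"`.
#' @export
make_skull_proxy <- function(params, subdivisions = 3) {
  sphere <- icosphere(subdivisions)
  u <- sphere$positions                       # unit directions
  axes <- c(0.8, 1.0, 0.9) * params$base_radius
  p <- u %*% diag(axes)                       # ellipsoid
  # brow bump: raised-cosine falloff in angle from the brow direction
  w <- normalize_rows(p)
  theta <- acos(pmin(1, pmax(-1, w %*% BROW_DIR)))
  patch <- which(theta < BROW_THETA)
  h <- numeric(nrow(p))
  h[patch] <- params$brow_amplitude *
    0.5 * (1 + cos(pi * theta[patch] / BROW_THETA))
  p <- p + h * w
  # lower-face widening: scale lateral (x) by a smooth ramp in height
  zeta <- u[, 3]                              # unit-sphere height
  ramp <- smoothstep((-0.15 - zeta) / 0.3)    # 0 above z=-0.15, 1 below -0.45
  p[, 1] <- p[, 1] * (1 + (params$jaw_width_factor - 1) * ramp)
  # radial noise
  if (params$noise_sd > 0) {
    p <- local_seed(params$rng_seed,
                    p + rnorm(nrow(p), 0, params$noise_sd) * normalize_rows(p))
  }
  out <- trimesh(p, sphere$faces)
  attr(out, "brow_patch") <- patch
  attr(out, "params") <- params
  out
}

#' Sample a labeled synthetic population
#'
#' Draws `n` labeled skull proxies with overlapping class distributions:
#' males get `base_radius ~ N(95, 4)` mm, `brow_amplitude ~ N(3, 1) *
#' sex_effect` mm and `jaw_width_factor ~ N(1.06, 0.02)`; females
#' `N(90, 4)`, `N(1, 1) * sex_effect` and `N(1.00, 0.02)`. Negative brow
#' draws are clamped at 0. Labels are balanced (ceiling(n/2) males, label
#' 0, then females, label 1).
#'
#' @param n number of samples, >= 2.
#' @param sex_effect scales the brow-amplitude dimorphism (0 removes it).
#' @param noise_sd per-mesh radial noise sd in mm.
#' @param rng_seed integer seed; the whole set is reproducible from it.
#' @param subdivisions passed to [make_skull_proxy()].
#' @param size_dimorphism,jaw_dimorphism set `FALSE` to force the male
#'   distribution of that feature to equal the female one (for null
#'   experiments).
#' @return object of class `labeled_mesh_set`: list with `meshes`,
#'   `labels` (integer 0/1), `params` (list of [shape_params()]).
#' @export
sample_population <- function(n, sex_effect = 1, noise_sd = 0.5,
                              rng_seed = 1L, subdivisions = 3,
                              size_dimorphism = TRUE,
                              jaw_dimorphism = TRUE) {
  if (n < 2) stopf("n must be >= 2")
  n_male <- ceiling(n / 2)
  labels <- c(rep(0L, n_male), rep(1L, n - n_male))
  params <- local_seed(rng_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      male <- labels[i] == 0L
      size_mu <- if (male && size_dimorphism) 95 else 90
      brow_mu <- if (male) 3 else 1
      jaw_mu <- if (male && jaw_dimorphism) 1.06 else 1.00
      shape_params(
        base_radius = max(1, rnorm(1, size_mu, 4)),
        brow_amplitude = max(0, rnorm(1, brow_mu, 1)) * sex_effect,
        jaw_width_factor = rnorm(1, jaw_mu, 0.02),
        noise_sd = noise_sd, rng_seed = seeds[i], label = labels[i])
    })
  })
  meshes <- lapply(params, make_skull_proxy, subdivisions = subdivisions)
  structure(list(meshes = meshes, labels = labels, params = params),
            class = "labeled_mesh_set")
}

#' @export
print.labeled_mesh_set <- function(x, ...) {
  cat(sprintf("labeled_mesh_set: %d meshes (%d male / %d female)\n",
              length(x$meshes), sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' Geometric feature estimates of a skull proxy
#'
#' Pose-normalized (PCA-axis) estimates of the three dimorphic features,
#' measured from the mesh alone:
#' * `brow` — mean radial excess (mm) over the least-squares-fitted
#'   ellipsoid inside the brow patch. The in-plane orientation of the
#'   principal axes is the sign combination maximizing this excess, which
#'   anchors "upper front" to the most brow-like region of the shape.
#' * `jaw` — ratio of lower-third to upper-third lateral width (mean of
#'   the top decile of |lateral coordinate| in each band).
#' * `size` — mean vertex distance from the centroid (mm), a smooth,
#'   perturbation-stable proxy for global size.
#'
#' @param mesh a [trimesh].
#' @return named numeric vector `c(brow =, jaw =, size =)`.
#' @export
proxy_features <- function(mesh) {
  P <- mesh$positions
  X <- sweep(P, 2, colMeans(P))
  pc <- stats::prcomp(X, center = FALSE)
  # columns ordered by decreasing variance: front-back, vertical, lateral
  Y <- X %*% pc$rotation
  r <- row_norms(Y)
  # least-squares ellipsoid radii: fit a1*y1^2 + a2*y2^2 + a3*y3^2 = 1
  M <- Y^2
  coefs <- solve(crossprod(M), colSums(M))
  radii <- 1 / sqrt(pmax(coefs, 1e-12))
  u <- Y / r
  pred_r <- 1 / sqrt((u[, 1] / radii[1])^2 + (u[, 2] / radii[2])^2 +
                       (u[, 3] / radii[3])^2)
  excess <- r - pred_r
  d_front <- BROW_DIR[2]
  d_up <- BROW_DIR[3]
  best <- list(val = -Inf, s1 = 1, s2 = 1)
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    cosang <- s1 * u[, 1] * d_front + s2 * u[, 2] * d_up
    in_patch <- cosang > cos(BROW_THETA)
    val <- if (any(in_patch)) mean(excess[in_patch]) else -Inf
    if (val > best$val) best <- list(val = val, s1 = s1, s2 = s2)
  }
  brow <- best$val
  up <- best$s2 * Y[, 2]
  lat <- abs(Y[, 3])
  band_width <- function(idx) {
    w <- lat[idx]
    mean(w[w >= quantile(w, 0.9)])
  }
  lower <- up < -radii[2] / 3
  upper <- up > radii[2] / 3
  jaw <- if (any(lower) && any(upper)) band_width(lower) / band_width(upper)
         else 1
  c(brow = brow, jaw = jaw, size = mean(r))
}

# standardization constants for the analytic scorer, calibrated once by
# Monte Carlo against the default population distributions (pooled mean
# and sd of each feature estimate); see the methods vignette
SCORER_CAL <- list(
  brow = c(mu = 0.398, sd = 0.259),
  jaw  = c(mu = 1.018, sd = 0.0387),
  size = c(mu = 83.7,  sd = 4.61),
  w    = c(brow = 1.5, jaw = 1.0, size = 1.0))

#' Analytic scoring function for skull proxies
#'
#' A deterministic stand-in for a trained classifier, so gradient maps have
#' a known ground truth: `P(female) = plogis(-(w_b z_b + w_j z_j + w_s
#' z_s))`, where `z_b`, `z_j`, `z_s` are standardized, winsorized-at-±3
#' [proxy_features()]
#' (brow excess, jaw width ratio, mean radius) — each a masculine-
#' increasing trait, hence the negative sign. Weights are fixed at (1.5,
#' 1.0, 1.0), the brow weighted highest as the leading localized dimorphic
#' trait; standardization constants are frozen calibrations against the
#' default population distributions. Pose normalization makes the score
#' rigid-rotation invariant.
#'
#' @return a [scoring_function()] named `"analytic"`.
#' @export
analytic_scorer <- function() {
  scoring_function(function(mesh) {
    f <- proxy_features(mesh)
    cal <- SCORER_CAL
    z <- c((f["brow"] - cal$brow["mu"]) / cal$brow["sd"],
           (f["jaw"] - cal$jaw["mu"]) / cal$jaw["sd"],
           (f["size"] - cal$size["mu"]) / cal$size["sd"])
    # winsorize so no single feature dominates far outside the
    # calibration regime (e.g. very large brow amplitudes)
    z <- pmax(-3, pmin(3, z))
    unname(stats::plogis(-sum(cal$w * z)))
  }, name = "analytic")
}

#' Export a labeled population as STL files plus a CSV manifest
#'
#' @param population a `labeled_mesh_set`.
#' @param dir output directory (created if missing).
#' @param force overwrite a non-empty directory.
#' @return path to the manifest CSV, invisibly.
#' @export
export_population <- function(population, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stopf("output directory %s is not empty (use force = TRUE)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(population$meshes)
  files <- sprintf("proxy_%03d.stl", seq_len(n))
  for (i in seq_len(n))
    write_stl(population$meshes[[i]], file.path(dir, files[i]))
  manifest <- data.frame(
    file = files,
    label = population$labels,
    base_radius = vapply(population$params, `[[`, 0, "base_radius"),
    brow_amplitude = vapply(population$params, `[[`, 0, "brow_amplitude"),
    jaw_width_factor = vapply(population$params, `[[`, 0,
                              "jaw_width_factor"),
    noise_sd = vapply(population$params, `[[`, 0, "noise_sd"),
    rng_seed = vapply(population$params, `[[`, 0L, "rng_seed"))
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
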