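# Mesh-space data augmentation: bounded random rotation, per-axis random
# shift, and random sagittal mirroring. Operating on vertices of the mesh
# is far cheaper than augmenting dense volumes, and the voxelizer is
# applied downstream of augmentation.

#' Augmentation configuration
#'
#' Defaults follow the standard mesh-augmentation recipe for skull
#' classification: rotation within +/- 10 degrees, shift within +/- 5% of
#' the per-axis bounding-box extent, mirroring with probability 0.5.
#'
#' @param max_rotation_deg rotation angle bound in degrees, >= 0.
#' @param max_shift_fraction shift bound as a fraction of the per-axis
#'   bounding-box extent, >= 0.
#' @param mirror_probability probability of applying the mirror, in \[0,1\].
#' @param rng_seed optional integer seed applied (locally) by [augment()].
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(max_rotation_deg = 10,
                                max_shift_fraction = 0.05,
                                mirror_probability = 0.5,
                                rng_seed = NULL) {
  if (max_rotation_deg < 0) stopf("max_rotation_deg must be >= 0")
  if (max_shift_fraction < 0) stopf("max_shift_fraction must be >= 0")
  if (mirror_probability < 0 || mirror_probability > 1)
    stopf("mirror_probability must be in [0, 1]")
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_shift_fraction = max_shift_fraction,
                 mirror_probability = mirror_probability,
                 rng_seed = rng_seed),
            class = "augmentation_config")
}

# Rodrigues rotation matrix for unit axis and angle (radians)
rotation_matrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random bounded rotation about the centroid
#'
#' Axis-angle parameterization: axis uniform on the sphere, angle uniform
#' in +/- `max_rotation_deg`. A single axis-angle draw keeps the total
#' rotation angle interpretably bounded, which composed per-axis Euler
#' rotations would not. The rotation is about the centroid so it does not
#' alias into a translation. Draws come from the current RNG stream.
#'
#' @param mesh a [trimesh].
#' @param config an [augmentation_config()].
#' @return the rotated [trimesh], with the applied 3 x 3 matrix in
#'   attribute `"rotation"`.
#' @export
random_rotation <- function(mesh, config = augmentation_config()) {
  if (config$max_rotation_deg == 0) {
    out <- mesh
    attr(out, "rotation") <- diag(3)
    return(out)
  }
  axis <- rnorm(3)
  while (sum(axis^2) < 1e-12) axis <- rnorm(3)
  angle <- runif(1, -config$max_rotation_deg, config$max_rotation_deg) *
    pi / 180
  R <- rotation_matrix(axis, angle)
  ctr <- mesh_centroid(mesh)
  pos <- sweep(mesh$positions, 2, ctr) %*% t(R)
  out <- trimesh(sweep(pos, 2, ctr, "+"), mesh$faces, mesh$provenance)
  attr(out, "rotation") <- R
  out
}

#' Random bounded per-axis shift
#'
#' Each translation component is drawn independently and uniformly within
#' +/- `max_shift_fraction` of that axis's bounding-box extent ("size").
#' A degenerate zero-extent axis gets zero shift.
#'
#' @inheritParams random_rotation
#' @return the shifted [trimesh], with the applied translation in
#'   attribute `"shift"`.
#' @export
random_shift <- function(mesh, config = augmentation_config()) {
  ext <- apply(mesh$positions, 2, function(x) diff(range(x)))
  lim <- config$max_shift_fraction * ext
  shift <- ifelse(lim > 0, runif(3, -lim, lim), 0)
  out <- trimesh(sweep(mesh$positions, 2, shift, "+"), mesh$faces,
                 mesh$provenance)
  attr(out, "shift") <- shift
  out
}

mirror_positions <- function(positions, axis = "x", center = NULL) {
  j <- match(axis, c("x", "y", "z"))
  if (is.na(j)) stopf("mirror axis must be x, y or z")
  center <- center %||% colMeans(positions)
  positions[, j] <- 2 * center[j] - positions[, j]
  positions
}

#' Mirror a mesh about a centroid plane
#'
#' Reflects positions about the plane through the centroid orthogonal to
#' `axis` (default sagittal, x) and reverses face winding so outward
#' normals stay outward. An involution: mirroring twice restores the mesh.
#'
#' @param mesh a [trimesh].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return the mirrored [trimesh].
#' @export
mirror_mesh <- function(mesh, axis = "x") {
  pos <- mirror_positions(mesh$positions, axis)
  faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  trimesh(pos, faces, mesh$provenance)
}

#' Random mirroring
#'
#' With probability `mirror_probability`, applies [mirror_mesh()] about the
#' sagittal (x) centroid plane; otherwise returns the mesh unchanged. The
#' branch taken is reported in attribute `"mirrored"`.
#'
#' @inheritParams random_rotation
#' @return a [trimesh] with logical attribute `"mirrored"`.
#' @export
random_mirror <- function(mesh, config = augmentation_config()) {
  flip <- config$mirror_probability > 0 &&
    runif(1) < config$mirror_probability
  out <- if (flip) mirror_mesh(mesh, "x") else mesh
  attr(out, "mirrored") <- flip
  out
}

#' Composite augmentation: rotate, shift, mirror
#'
#' Applies the three augmentations in order with consecutive draws from one
#' RNG stream. If `config$rng_seed` is set the stream is seeded locally
#' (the caller's RNG state is preserved), making the output fully
#' reproducible; vertex and face counts are always preserved.
#'
#' @inheritParams random_rotation
#' @return the augmented [trimesh]; attributes `"rotation"`, `"shift"`,
#'   `"mirrored"` record the applied transforms.
#' @export
augment <- function(mesh, config = augmentation_config()) {
  local_seed(config$rng_seed, {
    m1 <- random_rotation(mesh, config)
    m2 <- random_shift(m1, config)
    m3 <- random_mirror(m2, config)
    attr(m3, "rotation") <- attr(m1, "rotation")
    attr(m3, "shift") <- attr(m2, "shift")
    m3
  })
}
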