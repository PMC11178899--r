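# Mesh -> dense binary occupancy volume, the input representation for
# volumetric CNNs. Conservative (intersection-based) surface voxelization
# guarantees watertight shells, so closed meshes can be filled solid.

#' Voxel grid container
#'
#' @param occupancy logical 3D array (resolution^3).
#' @param origin mm coordinates of the minimum corner of voxel (1,1,1).
#' @param voxel_size edge length of a voxel in mm (isotropic).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(occupancy, origin, voxel_size) {
  stopifnot(length(dim(occupancy)) == 3L, voxel_size > 0,
            length(origin) == 3L)
  structure(list(occupancy = occupancy, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size),
                 resolution = dim(occupancy)[1]),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d^3, voxel %.4g mm, %d occupied\n",
              x$resolution, x$voxel_size, sum(x$occupancy)))
  invisible(x)
}

voxel_grid_frame <- function(mesh, resolution) {
  bb <- apply(mesh$positions, 2, range)
  extent <- max(bb[2, ] - bb[1, ])
  if (extent <= 0) stopf("degenerate mesh bounding box")
  center <- colMeans(bb)
  s <- extent / resolution
  origin <- center - extent / 2
  list(origin = origin, s = s)
}

#' Conservative surface voxelization
#'
#' The grid is a cube spanning the largest bounding-box extent, centered on
#' the bounding box, at `resolution` voxels per axis. A voxel is occupied
#' iff its cube intersects any triangle (separating-axis test); voxels are
#' half-open per axis, so a triangle lying exactly on a shared voxel face
#' belongs to the lower voxel. Intersection-based occupancy (rather than
#' center sampling) makes the shell of a closed mesh watertight at any
#' resolution, which [fill_solid()] relies on.
#'
#' @param mesh a non-empty [trimesh].
#' @param resolution voxels per axis, >= 2.
#' @return a [voxel_grid()].
#' @export
voxelize_surface <- function(mesh, resolution) {
  if (resolution < 2) stopf("resolution must be >= 2")
  if (n_faces(mesh) == 0L) stopf("cannot voxelize an empty mesh")
  fr <- voxel_grid_frame(mesh, resolution)
  occ <- .voxelize_surface_cpp(mesh$positions, mesh$faces, fr$origin,
                               fr$s, as.integer(resolution))
  dim(occ) <- rep(as.integer(resolution), 3)
  voxel_grid(occ, fr$origin, fr$s)
}

# 6-connected frontier growth, vectorized over the whole array
grow_once <- function(mask, free) {
  r <- dim(mask)[1]
  g <- mask
  g[-1, , ] <- g[-1, , ] | mask[-r, , ]
  g[-r, , ] <- g[-r, , ] | mask[-1, , ]
  g[, -1, ] <- g[, -1, ] | mask[, -r, ]
  g[, -r, ] <- g[, -r, ] | mask[, -1, ]
  g[, , -1] <- g[, , -1] | mask[, , -r]
  g[, , -r] <- g[, , -r] | mask[, , -1]
  g & free
}

#' Fill the interior of a voxelized shell
#'
#' Flood-fills the exterior (6-connected) from the grid boundary; every
#' voxel neither reached nor part of the shell becomes occupied. A leaky
#' shell lets the exterior flood inside and silently yields less filling;
#' the fraction of empty voxels reached by the exterior flood is attached
#' as attribute `"exterior_fraction"` for diagnosis, and a warning is
#' raised if nothing was filled despite a non-empty shell.
#'
#' @param grid a [voxel_grid()].
#' @return a [voxel_grid()] with interior voxels set. Idempotent.
#' @export
fill_solid <- function(grid) {
  occ <- grid$occupancy
  r <- dim(occ)[1]
  free <- !occ
  ext <- array(FALSE, dim(occ))
  ext[c(1, r), , ] <- TRUE
  ext[, c(1, r), ] <- TRUE
  ext[, , c(1, r)] <- TRUE
  ext <- ext & free
  repeat {
    grown <- grow_once(ext, free)
    if (sum(grown) == sum(ext)) break
    ext <- grown
  }
  filled <- occ | (!ext & free)
  n_new <- sum(filled) - sum(occ)
  if (n_new == 0L && sum(occ) > 0L && any(free))
    warning(sprintf("nothing filled: shell may be leaky (exterior reached %.1f%% of empty voxels)",
                    100 * sum(ext) / max(1, sum(free))))
  out <- voxel_grid(filled, grid$origin, grid$voxel_size)
  attr(out, "exterior_fraction") <- sum(ext) / max(1, sum(free))
  out
}

#' Write / read a voxel grid
#'
#' The volume goes to a flat binary file of uint8 (0/1, x fastest), with a
#' small text sidecar (`<path>.hdr`) in NRRD-style detached-header spirit
#' recording resolution, origin and voxel size.
#'
#' @param grid a [voxel_grid()].
#' @param path output path for the raw volume.
#' @return `path`, invisibly.
#' @export
write_voxels <- function(grid, path) {
  con <- file(path, "wb")
  writeBin(as.raw(as.integer(grid$occupancy)), con)
  close(con)
  writeLines(c(sprintf("resolution: %d", grid$resolution),
               sprintf("origin: %.17g %.17g %.17g", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("voxel_size: %.17g", grid$voxel_size),
               "encoding: raw uint8, x fastest"),
             paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_voxels
#' @export
read_voxels <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getv <- function(key) sub(paste0(key, ": "), "",
                            grep(paste0("^", key, ":"), hdr, value = TRUE))
  res <- as.integer(getv("resolution"))
  origin <- as.numeric(strsplit(getv("origin"), " ")[[1]])
  vs <- as.numeric(getv("voxel_size"))
  occ <- as.integer(readBin(path, "raw", res^3)) > 0L
  dim(occ) <- rep(res, 3)
  voxel_grid(occ, origin, vs)
}
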