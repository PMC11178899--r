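# fixture meshes built in code

make_tetra <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  # outward winding
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(v, f)
}

# unit cube [0,1]^3, 8 vertices, 12 faces, outward winding
make_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  trimesh(v, f)
}

# a line of collinear unit-spaced vertices stitched into degenerate-free
# triangles is awkward; for path-graph tests build a thin triangle strip
# whose edge graph contains the path 1-2-3-...-n with unit edges
make_path_strip <- function(n) {
  main <- cbind(seq_len(n) - 1, 0, 0)
  off <- cbind(seq_len(n - 1) - 0.5, 5, 0)  # far offset: shortest paths stay on the spine
  v <- rbind(main, off)
  f <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L, n + seq_len(n - 1))
  trimesh(v, f)
}

# random closed manifold mesh: jittered, randomly rotated/scaled icosphere
random_mesh <- function(seed, subdivisions = 1, radial_jitter = 0.1) {
  local_seed_test(seed, {
    m <- icosphere(subdivisions)
    r <- 1 + runif(n_vertices(m), -radial_jitter, radial_jitter)
    pos <- m$positions * r
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    scale <- runif(1, 0.5, 30)
    trimesh(pos %*% t(R) * scale, m$faces)
  })
}

local_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# scorer that counts its invocations (for call-budget tests)
counting_scorer <- function(value = 0.5) {
  env <- new.env()
  env$count <- 0L
  fn <- scoring_function(function(mesh) {
    env$count <- env$count + 1L
    value
  }, name = "counting")
  list(scorer = fn, env = env)
}

# clamp helper for analytic test scorers
clamp01 <- function(x) min(1, max(0, x))

# face multiset as a canonical character vector (geometry, not indexing)
face_multiset <- function(mesh, digits = 6) {
  fmt <- paste0("%.", digits, "g")
  tri <- lapply(seq_len(n_faces(mesh)), function(i) {
    m <- mesh$positions[mesh$faces[i, ], , drop = FALSE]
    m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    paste(sprintf(fmt, m), collapse = " ")
  })
  sort(unlist(tri))
}

# brute-force exhaustive all-pairs shortest path oracle (Floyd-Warshall)
apsp_oracle <- function(mesh) {
  n <- n_vertices(mesh)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  w <- sqrt(rowSums((mesh$positions[e[, 1], , drop = FALSE] -
                       mesh$positions[e[, 2], , drop = FALSE])^2))
  for (i in seq_len(nrow(e))) {
    D[e[i, 1], e[i, 2]] <- min(D[e[i, 1], e[i, 2]], w[i])
    D[e[i, 2], e[i, 1]] <- D[e[i, 1], e[i, 2]]
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# independent pure-R triangle/box SAT, exhaustive over ALL voxels of the
# grid frame; vectorized over voxel centers, one triangle at a time
voxelize_oracle <- function(mesh, resolution) {
  bb <- apply(mesh$positions, 2, range)
  extent <- max(bb[2, ] - bb[1, ])
  center <- colMeans(bb)
  s <- extent / resolution
  origin <- center - extent / 2
  half <- s / 2
  idx <- as.matrix(expand.grid(i = seq_len(resolution),
                               j = seq_len(resolution),
                               k = seq_len(resolution)))
  centers <- sweep((idx - 0.5) * s, 2, origin, "+")
  occ_flat <- rep(FALSE, nrow(centers))
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (f in seq_len(n_faces(mesh))) {
    tv <- mesh$positions[mesh$faces[f, ], , drop = FALSE]
    e <- rbind(tv[2, ] - tv[1, ], tv[3, ] - tv[2, ], tv[1, ] - tv[3, ])
    axes <- rbind(diag(3), cross3(e[1, ], e[2, ]))
    for (a in 1:3) for (k in 1:3)
      axes <- rbind(axes, cross3(diag(3)[a, ], e[k, ]))
    separated <- rep(FALSE, nrow(centers))
    for (ax in seq_len(nrow(axes))) {
      axis <- axes[ax, ]
      if (sum(abs(axis)) < 1e-300) next
      p <- as.vector(tv %*% axis)
      r <- half * sum(abs(axis))
      cproj <- as.vector(centers %*% axis)
      separated <- separated |
        (min(p) - cproj > r) | (max(p) - cproj < -r)
      if (all(separated | occ_flat)) break
    }
    occ_flat <- occ_flat | !separated
  }
  array(occ_flat, rep(resolution, 3))
}
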