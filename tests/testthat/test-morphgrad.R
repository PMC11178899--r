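test_that("linear falloff: endpoints, clamp, and linearity", {
  for (R in c(0.1, 1, 10, 100)) {
    expect_identical(sigma_falloff(0, R), 1)
    expect_identical(sigma_falloff(R, R), 0)
    expect_identical(sigma_falloff(2 * R, R), 0)
  }
  expect_equal(sigma_falloff(2.5, 10), 0.75)
  r <- seq(0, 10, by = 0.5)
  expect_equal(sigma_falloff(r, 10), (10 - r) / 10)
  expect_error(sigma_falloff(-1, 10), "negative")
  expect_error(sigma_falloff(1, 0), "range_R")
})

test_that("deform moves vertices along input normals with bounded support", {
  sph <- icosphere(2)
  apex <- which.max(sph$positions[, 3])

  # delta = 0 is the identity
  d0 <- deform(sph, apex, deformation_spec(delta = 0, range_R = 5))
  expect_identical(d0$positions, sph$positions)

  # range below the minimum edge length: only the center moves, radially
  min_edge <- min(sqrt(rowSums((sph$positions[sph$faces[, 1], ] -
                                  sph$positions[sph$faces[, 2], ])^2)))
  d1 <- deform(sph, apex, deformation_spec(delta = 0.1,
                                           range_R = min_edge * 0.9))
  moved <- which(rowSums(abs(d1$positions - sph$positions)) > 0)
  expect_identical(moved, apex)
  expect_equal(sqrt(sum(d1$positions[apex, ]^2)), 1.1, tolerance = 1e-3)

  # whole-sphere support: every vertex pushed outward by delta*sigma,
  # verified per vertex by brute force
  spec <- deformation_spec(delta = 0.1, range_R = 10)
  d2 <- deform(sph, apex, spec)
  radii <- sqrt(rowSums(d2$positions^2))
  expect_true(all(radii > 1.08 - 0.03 & radii < 1.1 + 1e-9))
  nrm <- vertex_normals(sph)
  dist <- sqrt(rowSums((sph$positions -
                          rep(sph$positions[apex, ], each = n_vertices(sph)))^2))
  expected <- sph$positions + 0.1 * sigma_falloff(dist, 10) * nrm
  attr(expected, "zero_normal") <- NULL
  expect_equal(d2$positions, expected, tolerance = 1e-12)

  # never farther than |delta|, never outside range_R
  spec3 <- deformation_spec(delta = -0.3, range_R = 0.8)
  d3 <- deform(sph, apex, spec3)
  step <- sqrt(rowSums((d3$positions - sph$positions)^2))
  expect_true(all(step <= 0.3 + 1e-12))
  expect_true(all(step[dist >= 0.8] == 0))
  expect_identical(d3$faces, sph$faces)
})

test_that("geodesic distance mode confines deformation to the surface patch", {
  sph <- icosphere(2)
  apex <- which.max(sph$positions[, 3])
  spec <- deformation_spec(delta = 0.1, range_R = 1.2,
                           distance_mode = "geodesic")
  d <- deform(sph, apex, spec)
  moved <- rowSums(abs(d$positions - sph$positions)) > 0
  gd <- graph_geodesic_distances(sph, apex, cutoff = 100)
  onpath <- as.numeric(gd[as.character(which(moved))])
  expect_true(all(onpath < 1.2))
  # graph distance >= Euclidean: the geodesic support is a subset
  euc <- deform(sph, apex, deformation_spec(0.1, 1.2))
  moved_euc <- rowSums(abs(euc$positions - sph$positions)) > 0
  expect_true(all(which(moved) %in% which(moved_euc)))
})

test_that("gradient at a vertex equals the score difference, with exact max-z case", {
  sph <- icosphere(2)
  apex <- which.max(sph$positions[, 3])
  maxz <- scoring_function(function(m) clamp01((max(m$positions[, 3]) + 2) / 4),
                           name = "maxz")
  # a tight bump moves only the apex, along its (near-+z) normal, so the
  # max z rises by exactly delta times the normal's z component
  g <- morphological_gradient_at(sph, maxz, apex,
                                 deformation_spec(delta = 0.05,
                                                  range_R = 0.05))
  nz <- vertex_normals(sph)[apex, 3]
  expect_gt(nz, 0.8)
  expect_equal(g, 0.05 * nz / 4, tolerance = 1e-12)

  const <- scoring_function(function(m) 0.5, "const")
  expect_identical(morphological_gradient_at(sph, const, apex,
                                             deformation_spec(2, 5)), 0)
  expect_identical(morphological_gradient_at(sph, maxz, apex,
                                             deformation_spec(0, 5)), 0)

  bad <- scoring_function(function(m) 1.5, "bad")
  expect_error(gradient_field(sph, bad, deformation_spec(1, 1), rho = 1),
               "contract")
})

test_that("gradient field: zero under constant scorers, dense when rho is tiny", {
  for (seed in 1:3) {
    m <- random_mesh(seed)
    f <- gradient_field(m, scoring_function(function(x) 0.31, "c"),
                        deformation_spec(1, 2), rho = 1)
    expect_identical(f$values, rep(0, n_vertices(m)))
  }
  sph <- icosphere(1)
  maxz <- scoring_function(function(m) clamp01((max(m$positions[, 3]) + 2) / 4),
                           "maxz")
  spec <- deformation_spec(0.05, 0.4)
  dense <- vapply(seq_len(n_vertices(sph)), function(v)
    morphological_gradient_at(sph, maxz, v, spec), numeric(1))
  f <- gradient_field(sph, maxz, spec, rho = 1e-9)
  expect_length(f$cover$cover_indices, n_vertices(sph))
  expect_equal(f$values, dense, tolerance = 1e-12)
})

test_that("scorer-call budget is exactly cover size + 1", {
  sph <- icosphere(1)
  cs <- counting_scorer()
  f <- gradient_field(sph, cs$scorer, deformation_spec(0.1, 1), rho = 0.8)
  expect_identical(cs$env$count, length(f$cover$cover_indices) + 1L)
})

test_that("gradient scales linearly in delta for a scorer linear in displacement", {
  sph <- icosphere(1)
  apex <- which.max(sph$positions[, 3])
  # mean z is linear in any vertex's z displacement
  meanz <- scoring_function(function(m) clamp01(0.5 + mean(m$positions[, 3])),
                            "meanz")
  spec1 <- deformation_spec(delta = 0.01, range_R = 0.3)
  spec2 <- deformation_spec(delta = 0.02, range_R = 0.3)
  g1 <- morphological_gradient_at(sph, meanz, apex, spec1)
  g2 <- morphological_gradient_at(sph, meanz, apex, spec2)
  expect_equal(g2 / g1, 2, tolerance = 1e-6)
})

test_that("sparse field sign agrees with dense evaluation on a smooth scorer", {
  sph <- icosphere(2)  # 162 vertices
  smooth <- scoring_function(function(m)
    clamp01(0.5 + mean(m$positions[, 3] * sqrt(rowSums(m$positions^2)))),
    "smooth")
  spec <- deformation_spec(0.08, 0.6)
  dense <- vapply(seq_len(n_vertices(sph)), function(v)
    morphological_gradient_at(sph, smooth, v, spec), numeric(1))
  f <- gradient_field(sph, smooth, spec, rho = 0.35)
  expect_lt(length(f$cover$cover_indices), n_vertices(sph))
  agree <- mean(sign(f$values) == sign(dense))
  expect_gte(agree, 0.9)
  expect_true(all(f$values >= min(dense) - 1e-12 &
                    f$values <= max(dense) + 1e-12))
})

test_that("region mask restricts evaluation and zeroes the outside", {
  sph <- icosphere(1)
  top <- which(sph$positions[, 3] > 0)
  cs <- counting_scorer()
  f <- gradient_field(sph, cs$scorer, deformation_spec(0.1, 1), rho = 0.4,
                      region_mask = top)
  expect_true(all(f$cover$cover_indices %in% top))
  expect_true(all(f$values[setdiff(seq_len(n_vertices(sph)), top)] == 0))
})

test_that("symmetrized field is symmetric for a symmetric configuration", {
  sph <- icosphere(1)
  const <- scoring_function(function(m) 0.25, "const")
  f <- symmetrized_field(sph, const, deformation_spec(0.1, 1), rho = 0.5)
  expect_identical(f$values, rep(0, n_vertices(sph)))

  # scorer depending only on |x| spread: mirror in x is a no-op, so the
  # symmetrized field matches the plain field at mirrored vertex pairs
  absx <- scoring_function(function(m)
    clamp01(0.5 + 0.2 * (mean(abs(m$positions[, 1])) - 0.5)), "absx")
  spec <- deformation_spec(0.1, 0.8)
  fs <- symmetrized_field(sph, absx, spec, rho = 0.4)
  refl <- sph$positions
  refl[, 1] <- -refl[, 1]
  partner <- vapply(seq_len(n_vertices(sph)), function(i)
    which.min(rowSums((sph$positions -
                         rep(refl[i, ], each = n_vertices(sph)))^2)),
    integer(1))
  expect_equal(fs$values, fs$values[partner], tolerance = 1e-6)
})
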