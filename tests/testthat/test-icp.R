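test_that("exact nearest neighbours match a brute-force all-pairs scan", {
  set.seed(31)
  target <- generate_bone(seed = 31, resolution = "coarse")
  q <- target$vertices[sample(n_vertices(target), 200), ] +
    matrix(stats::rnorm(600, 0, 5), 200, 3)
  nn <- nearest_neighbors(q, target, mode = "exact")
  # O(n^2) oracle
  brute <- apply(q, 1, function(p) {
    d2 <- colSums((t(target$vertices) - p)^2)
    which.min(d2)
  })
  expect_equal(nn$index, brute)
  expect_equal(nn$distance,
               sqrt(rowSums((q - target$vertices[brute, ])^2)))

  # a target vertex queried against its own mesh is at distance zero
  self <- nearest_neighbors(target$vertices[17, , drop = FALSE], target,
                            mode = "exact")
  expect_equal(self$distance, 0)
  expect_equal(self$index, 17L)
})

test_that("approximate search stays within its (1+eps) guarantee", {
  set.seed(32)
  target <- generate_bone(seed = 32, resolution = "coarse")
  q <- matrix(stats::runif(600, -30, 330), 200, 3)
  approx <- nearest_neighbors(q, target, mode = "approximate", eps = 0.1)
  exact <- nearest_neighbors(q, target, mode = "exact")
  expect_true(all(approx$distance <= (1 + 0.1) * exact$distance + 1e-12))
})

test_that("normal compatibility rejects opposite-facing surfaces", {
  # two coincident planes facing opposite ways: every correspondence is
  # 180 degrees incompatible
  a <- compute_vertex_normals(square_mesh())
  b <- square_mesh()
  b$faces <- b$faces[, c(1, 3, 2), drop = FALSE]  # flip winding: -z normals
  b <- compute_vertex_normals(b)
  nn <- nearest_neighbors(a$vertices, b, mode = "exact_normal_compatible",
                          query_normals = a$normals, angle_max = 45)
  expect_true(all(!nn$accepted))
  expect_error(fine_align(a, b), "rejected")
})

test_that("point-to-point estimator recovers known rigid motions", {
  pts <- generate_bone(seed = 33, resolution = "coarse")$vertices[1:100, ]
  ident <- estimate_rigid_point_to_point(pts, pts)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)

  tr <- osteopair:::with_seed(33, random_rigid())
  fit <- estimate_rigid_point_to_point(pts, transform_points(pts, tr))
  expect_lt(max(abs(fit$rotation - tr$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - tr$translation)), 1e-9)

  # 3 non-collinear points admit an exact fit
  s3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  t3 <- transform_points(s3, tr)
  fit3 <- estimate_rigid_point_to_point(s3, t3)
  expect_lt(max(abs(transform_points(s3, fit3) - t3)), 1e-9)

  expect_error(estimate_rigid_point_to_point(s3[1:2, ], t3[1:2, ]),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimate_rigid_point_to_point(line, line), "collinear")
})

test_that("point-to-plane estimator recovers normal displacements", {
  s <- compute_vertex_normals(sphere_mesh(rings = 15, segments = 24))
  ident <- estimate_rigid_point_to_plane(s$vertices, s$vertices, s$normals)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)

  # source displaced 0.1 mm along the sphere normals: a pure radial scale
  # has no rigid component, so the translational recovery is a shift moving
  # the displaced cloud back onto the planes
  shift <- c(0.1, 0, 0)
  displaced <- sweep(s$vertices, 2, shift, "+")
  fit <- estimate_rigid_point_to_plane(displaced, s$vertices, s$normals)
  expect_lt(max(abs(fit$translation + shift)), 1e-6)
  expect_lt(max(abs(fit$rotation - diag(3))), 1e-6)

  # all normals parallel: in-plane motion unconstrained
  sq <- compute_vertex_normals(square_mesh())
  pts <- rbind(sq$vertices, sq$vertices + 0.5, sq$vertices * 2)
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3)
  expect_error(estimate_rigid_point_to_plane(pts, pts, nrm),
               "unconstrained")
})

test_that("rough + fine alignment recovers arbitrary rigid re-posings", {
  b <- generate_bone(seed = 34)
  for (s in 1:2) {
    tr <- osteopair:::with_seed(s, random_rigid())
    moved <- apply_transform(b, tr)
    moved$id <- "moved"
    st <- alignment_settings(seed = s)
    rough <- rough_align(moved, b, st)
    fine <- fine_align(moved, b, rough$transform, st)
    back <- transform_points(moved$vertices, fine$transform)
    rms <- sqrt(mean(rowSums((back - b$vertices)^2)))
    expect_lt(rms, 1e-3)
  }
})

test_that("self-alignment is an exact fixed point", {
  b <- generate_bone(seed = 35, resolution = "coarse")
  rough <- rough_align(b, b, alignment_settings(seed = 1))
  expect_lt(rough$rms_residual, 1e-9)

  fine <- fine_align(b, b, identity_transform(), alignment_settings())
  expect_lt(fine$rms_residual, 1e-9)
  expect_lt(max(abs(fine$transform$rotation - diag(3))), 1e-6)
  expect_true(fine$converged)
})

test_that("multi-start rough alignment dominates a single start", {
  # near-axisymmetric shaft: a single PCA start can land in the flipped
  # basin; 20 starts must do at least as well
  p <- bone_params(seed = 36)
  p$curvature <- 0.2
  b <- generate_bone(p, resolution = "coarse")
  tr <- osteopair:::with_seed(36, random_rigid())
  moved <- apply_transform(b, tr)
  r1 <- rough_align(moved, b, alignment_settings(n_initial_positions = 1,
                                                 seed = 7))
  r20 <- rough_align(moved, b, alignment_settings(n_initial_positions = 20,
                                                  seed = 7))
  expect_lte(r20$rms_residual, r1$rms_residual + 1e-12)
})

test_that("point-to-point ICP with exact NN has a nonincreasing residual trace", {
  b <- generate_bone(seed = 37, resolution = "coarse")
  tr <- osteopair:::with_seed(37, random_rigid())
  moved <- transform_points(b$vertices[seq(1, n_vertices(b), by = 3), ], tr)
  run <- osteopair:::cpp_icp_p2p(moved, b$vertices, diag(3), c(0, 0, 0),
                                 max_iter = 60, tol = 0, eps = 0)
  expect_true(all(diff(run$trace) <= 1e-12))
})

test_that("registration is deterministic given the seed", {
  pop <- tiny_population(n_pairs = 1, seed = 38)
  L <- pop$lefts$meshes[[1]]
  R <- mirror_mesh(pop$rights$meshes[[1]])
  st <- alignment_settings(seed = 5)
  a1 <- rough_align(L, R, st)
  a2 <- rough_align(L, R, st)
  expect_identical(a1$residual_trace, a2$residual_trace)
  f1 <- fine_align(L, R, a1$transform, st)
  f2 <- fine_align(L, R, a2$transform, st)
  expect_identical(f1$residual_trace, f2$residual_trace)
})

test_that("fine alignment tracks the surface noise floor", {
  set.seed(39)
  b <- compute_vertex_normals(generate_bone(seed = 39,
                                            resolution = "coarse"))
  noisy <- b
  noisy$vertices <- b$vertices +
    stats::rnorm(n_vertices(b), 0, 0.2) * b$normals
  noisy$normals <- NULL
  noisy$id <- "noisy"
  fine <- fine_align(noisy, b, identity_transform(), alignment_settings())
  expect_lt(fine$rms_residual, 3 * 0.2)
})

test_that("overlap trimming shields the registration from simulated damage", {
  set.seed(40)
  b <- generate_bone(seed = 40, resolution = "coarse")
  damaged <- b
  hit <- sample(n_vertices(b), round(0.3 * n_vertices(b)))
  damaged$vertices[hit, ] <- damaged$vertices[hit, ] + 10
  damaged$id <- "damaged"
  full <- fine_align(damaged, b, identity_transform(),
                     alignment_settings(overlap_fraction = 1))
  trimmed <- fine_align(damaged, b, identity_transform(),
                        alignment_settings(overlap_fraction = 0.7))
  expect_lt(trimmed$rms_residual, full$rms_residual)
})
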