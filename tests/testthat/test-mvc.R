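test_that("identical shapes in arbitrary poses compare to ~0 mm", {
  b <- generate_bone(seed = 50, resolution = "coarse")
  moved <- apply_transform(b, osteopair:::with_seed(50, random_rigid()))
  moved$id <- "copy"
  v <- mesh_to_mesh_value(b, moved, alignment_settings(seed = 1))
  expect_lt(v$value, 1e-3)
})

test_that("a uniform 0.5 mm radial offset reads back as ~0.5 mm", {
  s <- sphere_mesh(rings = 31, segments = 48, radius = 20, id = "a")
  s2 <- inflate_radial(s, 0.5)
  s2$id <- "b"
  v <- mesh_to_mesh_value(s, s2, alignment_settings(seed = 1))
  expect_equal(v$value, 0.5, tolerance = 0.05)
})

test_that("the value is symmetric and insensitive to copies", {
  pop <- tiny_population(n_pairs = 1, seed = 51, resolution = "coarse")
  L <- pop$lefts$meshes[[1]]
  R <- mirror_mesh(pop$rights$meshes[[1]])
  st <- alignment_settings(seed = 3)
  v_lr <- mesh_to_mesh_value(L, R, st)$value
  v_rl <- mesh_to_mesh_value(R, L, st)$value
  expect_lt(abs(v_lr - v_rl), 1e-6)

  # two bit-identical copies under different labels give the same value
  A <- L; A$id <- "a_copy1"
  B <- L; B$id <- "a_copy2"
  expect_lt(abs(mesh_to_mesh_value(A, R, st)$value -
                  mesh_to_mesh_value(B, R, st)$value), 1e-6)
})

test_that("the value is invariant to the initial pose", {
  pop <- tiny_population(n_pairs = 1, seed = 52, resolution = "coarse")
  L <- pop$lefts$meshes[[1]]
  R <- mirror_mesh(pop$rights$meshes[[1]])
  st <- alignment_settings(seed = 4)
  v0 <- mesh_to_mesh_value(L, R, st)$value
  for (s in 1:3) {
    L2 <- apply_transform(L, osteopair:::with_seed(s, random_rigid()))
    R2 <- apply_transform(R, osteopair:::with_seed(s + 10, random_rigid()))
    expect_lt(abs(mesh_to_mesh_value(L2, R2, st)$value - v0), 1e-6)
  }
})

test_that("the value grows monotonically with planted asymmetry", {
  sigmas <- c(0, 0.2, 0.5, 1.0)
  means <- sapply(sigmas, function(a) {
    mean(sapply(1:5, function(s) {
      p <- generate_population(population_config(
        n_pairs = 1, n_left_singletons = 0, n_right_singletons = 0,
        asymmetry_mm = a, surface_noise_mm = 0,
        mesh_resolution = "coarse", seed = s))
      mesh_to_mesh_value(p$lefts$meshes[[1]],
                         mirror_mesh(p$rights$meshes[[1]]),
                         alignment_settings(seed = s))$value
    }))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("compare_all fills the full matrix deterministically", {
  pop <- generate_population(population_config(
    n_pairs = 2, n_left_singletons = 0, n_right_singletons = 1,
    mesh_resolution = "coarse", seed = 53))
  st <- alignment_settings(seed = 53)
  cm <- compare_all(pop$lefts, pop$rights, st)
  expect_s3_class(cm, "comparison_matrix")
  expect_equal(dim(cm$values), c(2L, 3L))
  expect_true(all(is.finite(cm$values)))
  expect_true(all(cm$values >= 0))

  # planted structure: true-pair cells smallest in their row and column
  for (r in seq_len(nrow(pop$truth))) {
    l <- pop$truth$left_id[r]; ri <- pop$truth$right_id[r]
    if (is.na(l) || is.na(ri)) next
    expect_equal(which.min(cm$values[l, ]), match(ri, colnames(cm$values)),
                 ignore_attr = TRUE)
    expect_equal(which.min(cm$values[, ri]), match(l, rownames(cm$values)),
                 ignore_attr = TRUE)
  }

  # byte-identical CSV on rerun with the same seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_comparison_matrix(cm, f1)
  write_comparison_matrix(compare_all(pop$lefts, pop$rights, st), f2)
  expect_identical(readLines(f1), readLines(f2))

  # CSV round trip preserves ids and values to the printed precision
  back <- read_comparison_matrix(f1)
  expect_identical(dimnames(back$values), dimnames(cm$values))
  expect_equal(back$values, cm$values, tolerance = 1e-5)
})

test_that("deviation maps band signed distances correctly", {
  s <- sphere_mesh(rings = 21, segments = 32, radius = 15, id = "ref")
  dm0 <- deviation_map(s, s, band = 0.645)
  expect_true(all(dm0$signed_distance == 0))
  expect_true(all(dm0$band_label == "within"))

  bigger <- inflate_radial(s, 1)
  dm1 <- deviation_map(s, bigger, band = 0.645)
  expect_true(all(dm1$band_label == "larger"))
  expect_true(all(dm1$signed_distance > 0))

  smaller <- inflate_radial(s, -1)
  dm2 <- deviation_map(s, smaller, band = 0.645)
  expect_true(all(dm2$band_label == "smaller"))

  ply <- withr::local_tempfile(fileext = ".ply")
  write_deviation_ply(dm1, ply)
  expect_true(any(grepl("property float quality", readLines(ply))))
})

test_that("failed cells are recorded as NA without aborting the run", {
  # a flat square has no usable rough-alignment geometry against a bone in
  # normal-compatible fine alignment with opposite winding; force failure
  # through a mesh whose normals all disagree
  pop <- tiny_population(n_pairs = 1, seed = 54, resolution = "coarse")
  flipped <- pop$rights$meshes[[1]]
  flipped$faces <- flipped$faces[, c(1, 3, 2), drop = FALSE]  # inward normals
  rights <- specimen_set("right", list(flipped))
  cm <- compare_all(pop$lefts, rights, alignment_settings(seed = 1),
                    mirror = FALSE)
  expect_true(is.na(cm$values[1, 1]))
  expect_s3_class(cm$failures, "data.frame")
})
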