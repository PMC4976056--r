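test_that("OBJ files round-trip vertices and topology", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_equal(n_vertices(m2), 4L)
  expect_equal(n_faces(m2), 4L)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  expect_identical(m2$faces, m$faces)
})

test_that("STL input is welded to a shared vertex set", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path)  # ASCII STL: 12 facet-vertices on disk
  m2 <- read_mesh(path)
  expect_equal(n_vertices(m2), 4L)
  expect_equal(n_faces(m2), 4L)

  # brute-force O(n^2) coordinate dedup oracle on the raw facet vertices
  raw <- do.call(rbind, lapply(seq_len(nrow(m$faces)), function(i)
    m$vertices[m$faces[i, ], ]))
  n_unique <- 0L
  for (i in seq_len(nrow(raw))) {
    dup <- FALSE
    for (j in seq_len(i - 1L))
      if (max(abs(raw[i, ] - raw[j, ])) < 1e-8) { dup <- TRUE; break }
    if (!dup) n_unique <- n_unique + 1L
  }
  expect_equal(n_vertices(m2), n_unique)
})

test_that("welding is idempotent", {
  m <- tetra_mesh()
  w1 <- weld_vertices(m$vertices, m$faces, tol = 1e-8)
  w2 <- weld_vertices(w1$vertices, w1$faces, tol = 1e-8)
  expect_identical(w1, w2)
})

test_that("binary STL reads back the same mesh as ASCII STL", {
  m <- tetra_mesh()
  ascii <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, ascii)
  bin <- withr::local_tempfile(fileext = ".stl")
  con <- file(bin, "wb")
  writeBin(raw(80L), con)
  writeBin(nrow(m$faces), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(m$faces))) {
    tri <- m$vertices[m$faces[i, ], ]
    writeBin(c(0, 0, 0, as.numeric(t(tri))), con, size = 4L,
             endian = "little")
    writeBin(raw(2L), con)
  }
  close(con)
  ma <- read_mesh(ascii)
  mb <- read_mesh(bin)
  expect_equal(n_vertices(mb), n_vertices(ma))
  expect_lt(max(abs(mb$vertices - ma$vertices)), 1e-5)
})

test_that("PLY files round-trip", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  expect_identical(m2$faces, m$faces)
})

test_that("malformed meshes are rejected with format errors", {
  bad <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 NaN", "v 1 0 0", "v 0 1 0", "f 1 2 3"), bad)
  expect_error(read_mesh(bad), "non-finite")

  empty <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0"), empty)
  expect_error(read_mesh(empty), "empty mesh")

  expect_error(read_mesh(withr::local_tempfile(fileext = ".xyz")),
               "does not exist")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1, 2, 2))), "degenerate")
})

test_that("specimen sets load by side suffix and manifest override", {
  dir <- withr::local_tempdir()
  write_mesh(tetra_mesh("a_L"), file.path(dir, "a_L.obj"))
  write_mesh(tetra_mesh("b_R"), file.path(dir, "b_R.obj"))
  lefts <- load_specimen_set(dir, "left")
  expect_equal(length(lefts), 1L)
  expect_equal(names(lefts$meshes), "a_L")
  rights <- load_specimen_set(dir, "right")
  expect_equal(names(rights$meshes), "b_R")

  # manifest assigns a right side to a file without the suffix convention
  write_mesh(tetra_mesh("weird"), file.path(dir, "weird_name.stl"))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("id,path,side", "weird_name,weird_name.stl,right"), manifest)
  rset <- load_specimen_set(dir, "right", manifest = manifest)
  expect_equal(names(rset$meshes), "weird_name")
})

test_that("duplicate ids are an error", {
  dir <- withr::local_tempdir()
  write_mesh(tetra_mesh(), file.path(dir, "a_L.obj"))
  write_mesh(tetra_mesh(), file.path(dir, "b_L.obj"))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("id,path,side", "same,a_L.obj,left", "same,b_L.obj,left"),
             manifest)
  expect_error(load_specimen_set(dir, "left", manifest = manifest),
               "duplicate")
  expect_error(specimen_set("left", list(tetra_mesh("x"), tetra_mesh("x"))),
               "duplicate")
})

test_that("vertex normals are area-weighted, unit, outward", {
  sq <- compute_vertex_normals(square_mesh())
  expect_equal(sq$normals, matrix(rep(c(0, 0, 1), each = 4), 4, 3),
               ignore_attr = TRUE)

  s <- compute_vertex_normals(sphere_mesh(rings = 31, segments = 48))
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  ang <- acos(pmin(1, rowSums(s$normals * radial))) * 180 / pi
  expect_lt(max(ang), 1)
  expect_equal(sqrt(rowSums(s$normals^2)), rep(1, n_vertices(s)),
               tolerance = 1e-6)

  # winding flip on mirroring keeps normals outward
  sm <- compute_vertex_normals(mirror_mesh(sphere_mesh(rings = 31,
                                                       segments = 48)))
  radial_m <- sm$vertices / sqrt(rowSums(sm$vertices^2))
  expect_true(all(rowSums(sm$normals * radial_m) > 0))
})

test_that("isolated vertices get zero normals and are flagged", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5))
  m <- compute_vertex_normals(triangle_mesh(v, rbind(c(1, 2, 3))))
  expect_equal(m$normals[4, ], c(0, 0, 0))
  expect_equal(attr(m$normals, "isolated_vertices"), 4L)
})
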