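# Fixture meshes built in code.

# Regular tetrahedron with edge length sqrt(8), centred on the origin.
tetra_mesh <- function(id = "tetra") {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  m <- triangle_mesh(v, f, id = id)
  if (osteopair:::signed_volume(m) < 0)
    m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}

# Flat unit square in the z = 0 plane (2 triangles, CCW from +z).
square_mesh <- function(id = "square") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  triangle_mesh(v, f, id = id)
}

# Radially offset copy of a sphere-like mesh centred on the origin.
inflate_radial <- function(mesh, offset_mm) {
  r <- sqrt(rowSums(mesh$vertices^2))
  mesh$vertices <- mesh$vertices * (1 + offset_mm / r)
  mesh
}

random_rigid <- function() {
  rigid_transform(osteopair:::random_rotation(), stats::runif(3, -50, 50))
}

# A small pair population for pipeline tests.
tiny_population <- function(n_pairs = 3, seed = 1, resolution = "coarse",
                            asymmetry_mm = 0.3, noise = 0.05, ...) {
  generate_population(population_config(
    n_pairs = n_pairs, n_left_singletons = 0, n_right_singletons = 0,
    asymmetry_mm = asymmetry_mm, surface_noise_mm = noise,
    mesh_resolution = resolution, seed = seed, ...))
}
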