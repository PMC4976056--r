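# Seeded generator of long-bone-like surface meshes and populations of
# paired specimens with controlled bilateral asymmetry.  The shape family is
# a procedural tube with enlarged ends (shaft length, radius, bow, end
# sizes/eccentricities and a low-order radial modulation field), not an
# anatomical atlas: the matching problem depends only on the relative scales
# of within-pair vs between-individual variation.

resolution_grid <- function(resolution) {
  if (is.numeric(resolution)) {
    nv <- max(50, resolution)
    seg <- max(8L, round(sqrt(nv / 2)))
    rings <- max(6L, round(nv / seg))
    return(c(rings = rings, segments = seg))
  }
  switch(match.arg(resolution, c("coarse", "standard", "fine")),
         coarse = c(rings = 30L, segments = 20L),
         standard = c(rings = 62L, segments = 32L),
         fine = c(rings = 94L, segments = 48L))
}

#' Draw shape parameters for a synthetic long bone
#'
#' Parameters are drawn around a humerus-scale prototype (shaft length
#' ~300 mm, shaft radius ~10 mm, bowed shaft, enlarged eccentric ends).
#' `variation` scales the spread of every parameter; at `variation = 1` the
#' 2-sigma shaft-length range is roughly 280-320 mm.
#'
#' @param variation relative scale of the between-individual parameter
#'   spread.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return A named list of shape parameters accepted by [generate_bone()].
#' @export
bone_params <- function(variation = 1, seed = NULL) {
  draw <- function() {
    list(length = 300 + variation * stats::rnorm(1, 0, 10),
         shaft_radius = 10 + variation * stats::rnorm(1, 0, 1),
         curvature = 4 + variation * stats::rnorm(1, 0, 1.5),
         prox_scale = 2.1 + variation * stats::rnorm(1, 0, 0.15),
         dist_scale = 1.8 + variation * stats::rnorm(1, 0, 0.15),
         prox_ecc = 1.25 + variation * stats::rnorm(1, 0, 0.08),
         dist_ecc = 0.85 + variation * stats::rnorm(1, 0, 0.08),
         prox_width = 0.16 + variation * stats::rnorm(1, 0, 0.015),
         dist_width = 0.13 + variation * stats::rnorm(1, 0, 0.015),
         modulation = variation * stats::rnorm(6, 0, 0.02))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic long-bone mesh
#'
#' Builds a closed, watertight tube-with-epiphyses surface: a bowed shaft of
#' the requested length and radius, two enlarged eccentric ends, and a
#' low-order smooth radial modulation field.  Deterministic given the
#' parameters.  The `(u, phi)` surface coordinates of every vertex are kept
#' in the `"uv"` attribute so smooth deformation fields can be expressed on
#' the surface.
#'
#' @param params shape parameters from [bone_params()]; if `NULL`, drawn
#'   using `seed`.
#' @param resolution `"coarse"` (~600 vertices), `"standard"` (~2000),
#'   `"fine"` (~4500), or a target vertex count.
#' @param seed used only when `params` is `NULL`.
#' @param id mesh label.
#' @return A watertight [triangle_mesh()] with outward normals.
#' @export
generate_bone <- function(params = NULL, resolution = "standard",
                          seed = NULL, id = "bone") {
  if (is.null(params))
    params <- bone_params(seed = seed)
  g <- resolution_grid(resolution)
  rings <- g[["rings"]]
  seg <- g[["segments"]]
  u <- seq_len(rings) / (rings + 1)
  phi <- 2 * pi * (seq_len(seg) - 1L) / seg

  L <- params$length
  bump_p <- exp(-(u / params$prox_width)^2)
  bump_d <- exp(-((1 - u) / params$dist_width)^2)
  r_u <- params$shaft_radius *
    (1 + (params$prox_scale - 1) * bump_p + (params$dist_scale - 1) * bump_d)
  e_u <- 1 + (params$prox_ecc - 1) * bump_p + (params$dist_ecc - 1) * bump_d
  # spherical-cap taper closing the tube at both poles
  delta <- 0.12
  d_end <- pmin(u, 1 - u)
  taper <- ifelse(d_end >= delta, 1,
                  sqrt(pmax(0, 1 - ((delta - d_end) / delta)^2)))
  cx <- params$curvature * sin(pi * u)

  U <- rep(u, each = seg)
  P <- rep(phi, times = rings)
  cmod <- params$modulation
  modf <- 1 + sin(pi * U) *
    (cmod[1] * cos(P) + cmod[2] * sin(P) +
       cmod[3] * cos(2 * P) + cmod[4] * sin(2 * P) +
       cmod[5] * cos(3 * P) + cmod[6] * sin(3 * P))
  Ru <- rep(r_u, each = seg)
  Eu <- rep(e_u, each = seg)
  Tu <- rep(taper, each = seg)
  Cx <- rep(cx, each = seg)
  verts <- cbind(Cx + Tu * Ru * Eu * modf * cos(P),
                 Tu * Ru / Eu * modf * sin(P),
                 L * U)
  pole0 <- c(params$curvature * sin(0), 0, 0)
  pole1 <- c(params$curvature * sin(pi), 0, L)
  vertices <- rbind(pole0, verts, pole1)
  uv <- rbind(c(0, 0), cbind(U, P), c(1, 0))

  vid <- function(i, j) 1L + (i - 1L) * seg + ((j - 1L) %% seg) + 1L
  faces <- vector("list", 2L * (rings - 1L) * seg + 2L * seg)
  n <- 0L
  for (i in seq_len(rings - 1L)) {
    for (j in seq_len(seg)) {
      a <- vid(i, j); b <- vid(i, j + 1L)
      c2 <- vid(i + 1L, j); d <- vid(i + 1L, j + 1L)
      faces[[n + 1L]] <- c(a, b, c2)
      faces[[n + 2L]] <- c(c2, b, d)
      n <- n + 2L
    }
  }
  p0 <- 1L
  p1 <- nrow(vertices)
  for (j in seq_len(seg)) {
    faces[[n + 1L]] <- c(p0, vid(1L, j + 1L), vid(1L, j))
    faces[[n + 2L]] <- c(p1, vid(rings, j), vid(rings, j + 1L))
    n <- n + 2L
  }
  mesh <- triangle_mesh(vertices, do.call(rbind, faces), id = id)
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  attr(mesh, "uv") <- uv
  attr(mesh, "params") <- params
  mesh
}

#' UV sphere mesh
#'
#' Convenience fixture: a closed sphere of the given radius, useful for
#' analytic checks of registration and deviation maps.
#'
#' @param radius sphere radius (mm).
#' @param rings,segments grid resolution.
#' @param id mesh label.
#' @return A watertight [triangle_mesh()].
#' @export
sphere_mesh <- function(radius = 10, rings = 15L, segments = 24L,
                        id = "sphere") {
  # rings ordered with z increasing, matching the bone construction so the
  # same face winding yields consistent outward orientation
  theta <- pi * (rings + 1 - seq_len(rings)) / (rings + 1)
  phi <- 2 * pi * (seq_len(segments) - 1L) / segments
  Th <- rep(theta, each = segments)
  P <- rep(phi, times = rings)
  verts <- radius * cbind(sin(Th) * cos(P), sin(Th) * sin(P), cos(Th))
  vertices <- rbind(c(0, 0, -radius), verts, c(0, 0, radius))
  vid <- function(i, j) 1L + (i - 1L) * segments + ((j - 1L) %% segments) + 1L
  faces <- list()
  for (i in seq_len(rings - 1L)) {
    for (j in seq_len(segments)) {
      a <- vid(i, j); b <- vid(i, j + 1L)
      c2 <- vid(i + 1L, j); d <- vid(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, c2)
      faces[[length(faces) + 1L]] <- c(c2, b, d)
    }
  }
  p0 <- 1L
  p1 <- nrow(vertices)
  for (j in seq_len(segments)) {
    faces[[length(faces) + 1L]] <- c(p0, vid(1L, j + 1L), vid(1L, j))
    faces[[length(faces) + 1L]] <- c(p1, vid(rings, j), vid(rings, j + 1L))
  }
  mesh <- triangle_mesh(vertices, do.call(rbind, faces), id = id)
  if (signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Population configuration
#'
#' Defaults emulate a desk-scale study assemblage: 10 pairs plus three
#' singleton bones, bilateral asymmetry of 0.3 mm RMS, 0.05 mm surface
#' noise, and between-individual shape variation several times larger than
#' the asymmetry.
#'
#' @param n_pairs number of true left-right pairs.
#' @param n_left_singletons,n_right_singletons unpaired extra individuals
#'   contributing one side only.
#' @param individual_variation relative scale of the per-individual
#'   shape-parameter spread (see [bone_params()]).
#' @param asymmetry_mm RMS magnitude (mm) of the smooth left-right surface
#'   deformation field.
#' @param surface_noise_mm per-vertex jitter standard deviation (mm).
#' @param mesh_resolution vertex-count class, see [generate_bone()].
#' @param seed integer seed for all randomness.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_pairs = 10L, n_left_singletons = 2L,
                              n_right_singletons = 1L,
                              individual_variation = 1,
                              asymmetry_mm = 0.3, surface_noise_mm = 0.05,
                              mesh_resolution = "standard", seed = 1L) {
  stopifnot(n_pairs >= 0, n_left_singletons >= 0, n_right_singletons >= 0,
            n_pairs + n_left_singletons + n_right_singletons >= 1,
            individual_variation >= 0, asymmetry_mm >= 0,
            surface_noise_mm >= 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_left_singletons = as.integer(n_left_singletons),
                 n_right_singletons = as.integer(n_right_singletons),
                 individual_variation = individual_variation,
                 asymmetry_mm = asymmetry_mm,
                 surface_noise_mm = surface_noise_mm,
                 mesh_resolution = mesh_resolution,
                 seed = as.integer(seed)),
            class = "population_config")
}

# Smooth low-order displacement field on the (u, phi) surface grid, scaled
# to the requested RMS magnitude; applied along vertex normals.
asymmetry_field <- function(uv, rms_mm) {
  if (rms_mm <= 0) return(rep(0, nrow(uv)))
  a <- stats::rnorm(8)
  u <- uv[, 1]
  p <- uv[, 2]
  f <- a[1] * sin(pi * u) + a[2] * sin(2 * pi * u) +
    sin(pi * u) * (a[3] * cos(p) + a[4] * sin(p) +
                     a[5] * cos(2 * p) + a[6] * sin(2 * p)) +
    sin(2 * pi * u) * (a[7] * cos(p) + a[8] * sin(p))
  f * rms_mm / max(sqrt(mean(f^2)), 1e-12)
}

random_pose <- function(mesh) {
  transform <- rigid_transform(random_rotation(),
                               stats::runif(3, -100, 100))
  apply_transform(mesh, transform)
}

#' Generate a population of paired synthetic bones
#'
#' For each individual, shape parameters are drawn and the right-side bone
#' generated; the left side is the mirror image of a re-generated bone
#' displaced along its normals by a smooth asymmetry field scaled to
#' `asymmetry_mm` RMS plus per-vertex jitter.  Singleton individuals
#' contribute one side only.  Every mesh is finally re-posed by a random
#' rigid motion, so no two meshes share an initial placement.
#'
#' @param config a [population_config()].
#' @return A list with `lefts` and `rights` ([specimen_set()]s), `truth`
#'   (data frame `left_id`, `right_id`, `NA` marking singletons) and
#'   `config`.
#' @export
generate_population <- function(config = population_config()) {
  with_seed(config$seed, {
    n_ind <- config$n_pairs + config$n_left_singletons +
      config$n_right_singletons
    roles <- c(rep("pair", config$n_pairs),
               rep("left_only", config$n_left_singletons),
               rep("right_only", config$n_right_singletons))
    lefts <- list()
    rights <- list()
    truth <- list()
    for (i in seq_len(n_ind)) {
      params <- bone_params(config$individual_variation)
      lid <- sprintf("ind%02d_L", i)
      rid <- sprintf("ind%02d_R", i)
      make_left <- roles[i] %in% c("pair", "left_only")
      make_right <- roles[i] %in% c("pair", "right_only")
      if (make_right) {
        right <- generate_bone(params, config$mesh_resolution, id = rid)
        rights[[length(rights) + 1L]] <- random_pose(right)
      }
      if (make_left) {
        base <- generate_bone(params, config$mesh_resolution, id = lid)
        base <- compute_vertex_normals(base)
        disp <- asymmetry_field(attr(base, "uv"), config$asymmetry_mm)
        if (config$surface_noise_mm > 0)
          disp <- disp + stats::rnorm(n_vertices(base), 0,
                                      config$surface_noise_mm)
        base$vertices <- base$vertices + disp * base$normals
        base$normals <- NULL
        left <- mirror_mesh(base)
        left$id <- lid
        lefts[[length(lefts) + 1L]] <- random_pose(left)
      }
      truth[[i]] <- data.frame(
        left_id = if (make_left) lid else NA_character_,
        right_id = if (make_right) rid else NA_character_,
        stringsAsFactors = FALSE)
    }
    list(lefts = specimen_set("left", lefts),
         rights = specimen_set("right", rights),
         truth = do.call(rbind, truth),
         config = config)
  })
}
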