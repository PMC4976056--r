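# Two-stage rigid registration: multi-start subsampled point-to-point rough
# alignment followed by full-sampling point-to-plane fine alignment with
# exact nearest neighbours and normal compatibility.

alignment_result <- function(transform, trace, iterations, converged) {
  structure(list(transform = transform,
                 rms_residual = trace[length(trace)],
                 n_iterations_run = as.integer(iterations),
                 converged = isTRUE(converged),
                 residual_trace = as.numeric(trace)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: RMS residual %.6g mm after %d iterations (%s)\n",
              x$rms_residual, x$n_iterations_run,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Nearest-neighbour correspondences against a mesh
#'
#' Queries points against the vertex set of a target mesh.  `"exact"` returns
#' the true nearest vertex; `"approximate"` may return any vertex within
#' (1 + eps) of the true nearest distance (eps = 0.1, the fast search used by
#' the rough stage); `"exact_normal_compatible"` additionally flags a
#' correspondence as rejected when the angle between query and target normals
#' exceeds `angle_max`.
#'
#' @param query_points n x 3 matrix of query coordinates.
#' @param target a [triangle_mesh()].
#' @param mode search mode.
#' @param query_normals n x 3 matrix of query normals (required for the
#'   normal-compatible mode); zero rows are exempt from the test.
#' @param angle_max compatibility threshold in degrees.
#' @param eps approximation slack for `"approximate"` mode.
#' @return A list with `index` (target vertex index per query), `point`
#'   (matched target coordinates), `normal` (matched target normals, or
#'   `NULL`), `distance` (mm) and `accepted` (logical).
#' @export
nearest_neighbors <- function(query_points,
                              target,
                              mode = c("exact", "approximate",
                                       "exact_normal_compatible"),
                              query_normals = NULL,
                              angle_max = 45,
                              eps = 0.1) {
  mode <- match.arg(mode)
  query_points <- as.matrix(query_points)
  if (nrow(query_points) == 0L)
    return(list(index = integer(0), point = query_points, normal = NULL,
                distance = numeric(0), accepted = logical(0)))
  if (n_vertices(target) < 1L) stop("target mesh has no vertices")
  tn <- NULL
  if (mode == "exact_normal_compatible") {
    if (is.null(query_normals))
      stop("query_normals are required for exact_normal_compatible mode")
    target <- compute_vertex_normals(target)
    tn <- target$normals
  }
  res <- cpp_nn(target$vertices, query_points,
                eps = if (mode == "approximate") eps else 0,
                target_normals = tn,
                query_normals = if (is.null(tn)) NULL else
                  as.matrix(query_normals),
                cos_min = if (is.null(tn)) -2 else
                  cos(angle_max * pi / 180))
  list(index = res$index,
       point = target$vertices[res$index, , drop = FALSE],
       normal = if (is.null(tn)) NULL else tn[res$index, , drop = FALSE],
       distance = res$distance,
       accepted = res$accepted)
}

#' Least-squares rigid transform from point correspondences
#'
#' Closed-form Procrustes/SVD solution of `argmin_{R,t} sum w_i |R s_i + t -
#' q_i|^2`, with the reflection guarded away (determinant forced to +1).
#'
#' @param source_points,target_points n x 3 matrices of corresponding points.
#' @param weights optional nonnegative weights.
#' @return A [rigid_transform()] mapping source onto target.
#' @export
estimate_rigid_point_to_point <- function(source_points, target_points,
                                          weights = NULL) {
  source_points <- as.matrix(source_points)
  target_points <- as.matrix(target_points)
  if (nrow(source_points) < 3L)
    stop("degenerate geometry: need at least 3 correspondences")
  sv <- svd(scale(source_points, scale = FALSE))$d
  if (sv[2] <= 1e-10 * max(sv[1], .Machine$double.xmin))
    stop("degenerate geometry: correspondences are collinear")
  fit <- cpp_estimate_p2p(source_points, target_points, weights)
  rigid_transform(fit$R, fit$t)
}

#' Rigid transform from point-to-plane correspondences
#'
#' Minimises `sum ((R s_i + t - q_i) . n_i)^2` via the standard small-angle
#' linearisation solved as a 6-unknown least-squares system, then projects
#' the rotation back onto SO(3).  A system leaving a translation
#' unconstrained (for example, all target normals parallel) is an error
#' naming the unconstrained motions; rotations rendered unobservable by the
#' geometry alone (a sphere's rotational symmetry) are frozen at zero.
#'
#' @param source_points,target_points n x 3 matrices of corresponding points.
#' @param target_normals n x 3 matrix of unit normals at the target points.
#' @return A [rigid_transform()].
#' @export
estimate_rigid_point_to_plane <- function(source_points, target_points,
                                          target_normals) {
  source_points <- as.matrix(source_points)
  if (nrow(source_points) < 6L)
    stop("degenerate geometry: need at least 6 correspondences")
  fit <- cpp_estimate_p2pl(source_points, as.matrix(target_points),
                           as.matrix(target_normals))
  s <- fit$singular_values
  bad <- which(s <= 1e-9 * max(s))
  if (length(bad) > 0L) {
    # a null direction with a translation component leaves the solution
    # genuinely indeterminate; pure-rotation null directions (a sphere's
    # rotational symmetry) are frozen at zero instead
    desc <- character(0)
    for (k in bad) {
      v <- fit$V[, k]
      rot <- sqrt(sum(v[1:3]^2))
      tra <- sqrt(sum(v[4:6]^2))
      if (tra > 0.1) {
        desc <- c(desc,
                  paste0("translation along (",
                         paste(sprintf("%.2f", v[4:6] / tra),
                               collapse = ", "), ")"))
      } else if (rot > 0) {
        desc <- c(desc,
                  paste0("rotation about (",
                         paste(sprintf("%.2f", v[1:3] / rot),
                               collapse = ", "),
                         ") [frozen at zero]"))
      }
    }
    if (any(grepl("^translation", desc)))
      stop("degenerate geometry: unconstrained motion(s): ",
           paste(desc, collapse = "; "))
  }
  rigid_transform(fit$R, fit$t)
}

# Candidate starting rotations for the rough stage: principal-axes alignment
# composed with the 4-element axis-flip group (the 180-degree ambiguities of
# an elongated bone), then deterministic quasi-uniform rotations to fill the
# start budget.
initial_rotations <- function(source, target, n) {
  vs <- eigen(stats::cov(source$vertices), symmetric = TRUE)$vectors
  vt <- eigen(stats::cov(target$vertices), symmetric = TRUE)$vectors
  if (det(vs) < 0) vs[, 3] <- -vs[, 3]
  if (det(vt) < 0) vt[, 3] <- -vt[, 3]
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                diag(c(-1, -1, 1)))
  base <- lapply(flips[seq_len(min(n, 4L))],
                 function(f) vt %*% f %*% t(vs))
  if (n > 4L) {
    extra <- lapply(halton_rotations(n - 4L),
                    function(q) q %*% base[[1]])
    base <- c(base, extra)
  }
  base
}

#' Rough alignment: multi-start subsampled point-to-point ICP
#'
#' Pre-aligns centroids and principal axes, generates
#' `n_initial_positions` candidate starting rotations (principal-axes
#' alignment, its axis-flip group, and quasi-uniform rotations filling the
#' budget), then from each start runs point-to-point ICP with approximate
#' nearest neighbours on a fixed seeded subsample of the source vertices.
#' The candidate whose final transform scores the lowest RMS residual,
#' re-evaluated over all source vertices with exact nearest neighbours,
#' wins (the subsample steers each run but is too sparse to rank the
#' candidates reliably).  Deterministic given `settings$seed`.
#'
#' @param source,target [triangle_mesh()] objects.
#' @param settings an [alignment_settings()].
#' @return An `alignment_result` whose `transform` maps source coordinates
#'   into target coordinates; `rms_residual` is the winner's full-source
#'   exact-NN residual and `residual_trace` the winning run's per-iteration
#'   (subsampled) trace.
#' @export
rough_align <- function(source, target, settings = alignment_settings()) {
  if (n_vertices(source) == 0L || n_vertices(target) == 0L)
    stop("cannot align empty meshes")
  n <- n_vertices(source)
  m <- min(n, max(4L, ceiling(settings$rough_sampling * n)))
  sample_idx <- with_seed(settings$seed, sample.int(n, m))
  src <- source$vertices[sample_idx, , drop = FALSE]
  cs <- centroid(source)
  ct <- centroid(target)
  rots <- initial_rotations(source, target, settings$n_initial_positions)
  best <- NULL
  best_full <- Inf
  for (R0 in rots) {
    t0 <- ct - as.numeric(R0 %*% cs)
    run <- cpp_icp_p2p(src, target$vertices, R0, t0,
                       max_iter = settings$rough_iterations,
                       tol = settings$convergence_tol,
                       eps = settings$approx_eps)
    # candidates are ranked by their residual over ALL source vertices with
    # exact NN: the subsample steers each run but is too sparse to pick a
    # winner (it can prefer an end-for-end flip of a near-symmetric bone)
    moved <- transform_points(source$vertices,
                              rigid_transform(run$R, run$t))
    full_rms <- sqrt(mean(cpp_nn_dists(target$vertices, moved)^2))
    if (full_rms < best_full) {
      best_full <- full_rms
      best <- run
    }
    if (best_full < 1e-9) break  # cannot be improved meaningfully
  }
  res <- alignment_result(rigid_transform(best$R, best$t), best$trace,
                          best$iterations, best$converged)
  res$rms_residual <- best_full
  res
}

#' Fine alignment: point-to-plane ICP with normal compatibility
#'
#' Starting from `initial` (typically the rough-alignment result), runs
#' point-to-plane ICP using `fine_sampling` of the source vertices (default
#' all of them) against exact nearest target vertices.  Correspondences are
#' rejected when source and target normals disagree by more than
#' `normal_angle_max` degrees, and, when `overlap_fraction < 1`, trimmed to
#' the best fraction of residuals each iteration.  Motions unconstrained by
#' the current correspondences (e.g. rotation of a sphere about its centre)
#' are frozen rather than extrapolated.
#'
#' @param source,target [triangle_mesh()] objects.
#' @param initial a [rigid_transform()] mapping source into target.
#' @param settings an [alignment_settings()].
#' @return An `alignment_result`; its `transform` is the full composed map
#'   from original source coordinates into target coordinates.
#' @export
fine_align <- function(source, target, initial = identity_transform(),
                       settings = alignment_settings()) {
  source <- compute_vertex_normals(source)
  target <- compute_vertex_normals(target)
  n <- n_vertices(source)
  keep <- seq_len(n)
  iso <- attr(source$normals, "isolated_vertices")
  if (length(iso)) keep <- setdiff(keep, iso)
  if (settings$fine_sampling < 1) {
    m <- min(length(keep), max(6L, ceiling(settings$fine_sampling * n)))
    keep <- sort(with_seed(settings$seed + 1L,
                           sample(keep, m)))
  }
  run <- cpp_icp_p2pl(source$vertices[keep, , drop = FALSE],
                      source$normals[keep, , drop = FALSE],
                      target$vertices, target$normals,
                      initial$rotation, initial$translation,
                      max_iter = settings$fine_iterations,
                      tol = settings$convergence_tol,
                      cos_min = cos(settings$normal_angle_max * pi / 180),
                      overlap = settings$overlap_fraction)
  if (isTRUE(run$failed))
    stop("fine alignment failed: all correspondences rejected by the ",
         "normal-compatibility test")
  alignment_result(rigid_transform(run$R, run$t), run$trace,
                   run$iterations, run$converged)
}
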