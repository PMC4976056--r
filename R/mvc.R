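# The mesh-to-mesh value, the all-vs-all comparison matrix, and
# deviation-band maps.

#' Mesh-to-mesh value of a registered pair
#'
#' Runs the two-stage registration ([rough_align()] then [fine_align()]) and
#' summarises the residual surface difference as a single value in mm.  With
#' the default metric this is the symmetric RMS nearest-neighbour distance:
#' the square root of the mean of squared exact nearest-neighbour distances
#' pooled over both directions under the final transform, evaluated on all
#' vertices of both meshes with no normal rejection.  Lower = more similar;
#' zero iff the surfaces coincide.
#'
#' To make the value exactly symmetric in its arguments, the registration
#' direction is canonicalised: the mesh whose id sorts first is the moving
#' mesh.
#'
#' @param left a [triangle_mesh()] (a left-side element).
#' @param right_mirrored a [triangle_mesh()] (a right-side element already
#'   mirror-imaged, see [mirror_mesh()]).
#' @param settings an [alignment_settings()].
#' @return An object of class `mesh_to_mesh_value` with fields `left_id`,
#'   `right_id`, `value` (mm), `transform` (the final rigid map of the moving
#'   mesh, with attribute `"moving"` naming it), `rough` and `fine`
#'   (`alignment_result`s).
#' @export
mesh_to_mesh_value <- function(left, right_mirrored,
                               settings = alignment_settings()) {
  ids <- c(left$id, right_mirrored$id)
  if (order(ids)[1] == 1L) {
    source <- left; target <- right_mirrored
  } else {
    source <- right_mirrored; target <- left
  }
  rough <- rough_align(source, target, settings)
  fine <- fine_align(source, target, rough$transform, settings)
  moved <- transform_points(source$vertices, fine$transform)
  # distances are measured point-to-surface (nearest point on any triangle
  # of the other mesh), so the value characterises the surfaces themselves
  # rather than the vertex sampling
  d_st <- cpp_surface_dists(target$vertices, target$faces, moved)
  d_ts <- cpp_surface_dists(moved, source$faces, target$vertices)
  value <- switch(settings$value_metric,
    symmetric_rms = sqrt(mean(c(d_st, d_ts)^2)),
    mean_absolute = mean(c(d_st, d_ts)),
    hausdorff = max(d_st, d_ts),
    one_directional = sqrt(mean(d_st^2))
  )
  transform <- fine$transform
  attr(transform, "moving") <- source$id
  structure(list(left_id = left$id, right_id = right_mirrored$id,
                 value = value, transform = transform,
                 rough = rough, fine = fine),
            class = "mesh_to_mesh_value")
}

#' @export
print.mesh_to_mesh_value <- function(x, ...) {
  cat(sprintf("mesh-to-mesh value: %.4f mm  (%s vs %s)\n", x$value,
              x$left_id, x$right_id))
  invisible(x)
}

#' Comparison matrix container
#'
#' @param values numeric matrix of mesh-to-mesh values (mm), left ids as row
#'   names, right ids as column names; `NA` marks a failed registration.
#' @param failures optional data frame recording per-cell failures.
#' @param settings the [alignment_settings()] used, if known.
#' @return An object of class `comparison_matrix`.
#' @export
comparison_matrix <- function(values, failures = NULL, settings = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("comparison matrix needs left ids as rownames and right ids as colnames")
  if (any(values < 0, na.rm = TRUE))
    stop("mesh-to-mesh values must be nonnegative")
  structure(list(values = values, failures = failures,
                 settings = settings),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("comparison_matrix: %d left x %d right mesh-to-mesh values (mm)\n",
              nrow(x$values), ncol(x$values)))
  if (any(is.na(x$values)))
    cat(sprintf("  %d failed cell(s)\n", sum(is.na(x$values))))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
summary.comparison_matrix <- function(object, ...) {
  v <- object$values
  cat(sprintf("comparison_matrix %d x %d, %d failed cells\n", nrow(v),
              ncol(v), sum(is.na(v))))
  print(summary(as.numeric(v)))
  invisible(object)
}

#' All-vs-all mesh-to-mesh comparison
#'
#' Mirrors every right-side mesh once, then computes the full left x right
#' table of mesh-to-mesh values.  Each cell uses a seed derived
#' deterministically from the global seed and the two ids, so results are
#' independent of evaluation order.  A cell whose registration fails is
#' recorded as `NA` (a failure is diagnostic information, not evidence of
#' non-match) and the run continues.
#'
#' @param lefts,rights [specimen_set()]s.
#' @param settings an [alignment_settings()].
#' @param mirror mirror the right meshes first (default `TRUE`; set to
#'   `FALSE` if they are already mirror-imaged).
#' @param verbose print per-cell progress.
#' @return A [comparison_matrix()].
#' @export
compare_all <- function(lefts, rights, settings = alignment_settings(),
                        mirror = TRUE, verbose = FALSE) {
  if (length(lefts) == 0L || length(rights) == 0L)
    stop("both specimen sets must be nonempty")
  lids <- specimen_ids(lefts)
  rids <- specimen_ids(rights)
  mirrored <- lapply(rights$meshes, function(m) {
    mm <- if (mirror) mirror_mesh(m) else m
    compute_vertex_normals(mm)
  })
  lefts_n <- lapply(lefts$meshes, compute_vertex_normals)
  values <- matrix(NA_real_, length(lids), length(rids),
                   dimnames = list(lids, rids))
  failures <- list()
  for (i in seq_along(lids)) {
    for (j in seq_along(rids)) {
      s <- settings
      s$seed <- cell_seed(settings$seed, lids[i], rids[j])
      res <- tryCatch(
        mesh_to_mesh_value(lefts_n[[i]], mirrored[[j]], s),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(left_id = lids[i], right_id = rids[j],
                     message = conditionMessage(res),
                     stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("  %s vs %s: FAILED (%s)", lids[i], rids[j],
                          conditionMessage(res)))
      } else {
        values[i, j] <- res$value
        if (verbose)
          message(sprintf("  %s vs %s: %.4f mm", lids[i], rids[j],
                          res$value))
      }
    }
  }
  comparison_matrix(values,
                    failures = if (length(failures))
                      do.call(rbind, failures),
                    settings = settings)
}

#' Read / write a comparison matrix as CSV
#'
#' First column holds the left ids, the header row the right ids, cells the
#' values in mm with 6 significant digits; failed cells are written as `NA`.
#'
#' @param cm a [comparison_matrix()].
#' @param path CSV file path.
#' @return `read_comparison_matrix` returns a [comparison_matrix()].
#' @export
write_comparison_matrix <- function(cm, path) {
  v <- cm$values
  body <- matrix(ifelse(is.na(v), "NA",
                        formatC(signif(v, 6), format = "g", digits = 6)),
                 nrow(v), ncol(v))
  lines <- c(paste(c("left_id", colnames(v)), collapse = ","),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], body[i, ]), collapse = ","),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_comparison_matrix
#' @export
read_comparison_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed comparison matrix CSV '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("malformed comparison matrix CSV '", path,
         "': need a left_id column and at least one right column")
  v <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(v))
    stop("malformed comparison matrix CSV '", path,
         "': non-numeric cells")
  rownames(v) <- df[[1]]
  comparison_matrix(v)
}

#' Deviation map between two registered meshes
#'
#' For every vertex of the comparison mesh (after applying `transform`), the
#' signed distance to the nearest reference vertex, signed by the reference
#' normal direction: positive where the comparison surface lies outside the
#' reference.  Vertices are banded as `"within"` (|d| < `band`), `"larger"`
#' or `"smaller"`, mirroring the colour-coded deviation rendering used to
#' inspect regions of size difference between antimeres.
#'
#' @param reference,comparison [triangle_mesh()]es.
#' @param transform [rigid_transform()] from a completed alignment, mapping
#'   the comparison mesh onto the reference.
#' @param band band half-width in mm (default 0.645).
#' @return An object of class `deviation_map`: list with `signed_distance`
#'   (mm per comparison vertex), `band_label` (factor), `band`, and the
#'   transformed comparison `mesh`.
#' @export
deviation_map <- function(reference, comparison,
                          transform = identity_transform(), band = 0.645) {
  reference <- compute_vertex_normals(reference)
  comparison <- apply_transform(comparison, transform)
  nn <- cpp_nn(reference$vertices, comparison$vertices, eps = 0)
  ref_pt <- reference$vertices[nn$index, , drop = FALSE]
  ref_n <- reference$normals[nn$index, , drop = FALSE]
  sgn <- sign(rowSums((comparison$vertices - ref_pt) * ref_n))
  sgn[sgn == 0] <- 1
  d <- sgn * nn$distance
  lab <- factor(ifelse(abs(d) < band, "within",
                       ifelse(d > 0, "larger", "smaller")),
                levels = c("smaller", "within", "larger"))
  structure(list(signed_distance = d, band_label = lab, band = band,
                 mesh = comparison, reference_id = reference$id),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat(sprintf("deviation_map vs '%s': band +/- %.3f mm\n", x$reference_id,
              x$band))
  print(table(x$band_label))
  cat(sprintf("  signed distance (mm): min %.3f, median %.3f, max %.3f\n",
              min(x$signed_distance), stats::median(x$signed_distance),
              max(x$signed_distance)))
  invisible(x)
}

#' Write a deviation map as ASCII PLY
#'
#' Per-vertex scalar (`quality` = signed distance, mm) and integer band
#' label (-1 smaller, 0 within, 1 larger).
#'
#' @param dm a [deviation_map()].
#' @param path output `.ply` path.
#' @export
write_deviation_ply <- function(dm, path) {
  write_ply(dm$mesh, path, scalar = dm$signed_distance,
            scalar_name = "quality",
            label = as.integer(dm$band_label) - 2L, label_name = "band")
  invisible(path)
}
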