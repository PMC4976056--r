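#' Triangle surface mesh
#'
#' The unit of all comparison in the package: a triangulated surface with
#' vertex coordinates in millimetres, faces as vertex-index triples, and
#' (lazily computed) area-weighted per-vertex unit normals.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param id character label for the mesh.
#' @param normals optional numeric matrix of per-vertex unit normals; usually
#'   left `NULL` and computed on demand by [compute_vertex_normals()].
#' @param validate if `TRUE` (default) the invariants are checked: finite
#'   coordinates, valid face indices, no degenerate faces.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `id`, `vertices`, `faces` and `normals`.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
#' m <- triangle_mesh(v, f, id = "tetra")
#' n_vertices(m)
#' @export
triangle_mesh <- function(vertices, faces, id = "mesh", normals = NULL,
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(id = as.character(id), vertices = vertices,
                         faces = faces, normals = normals),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) stop("empty mesh: no faces (id '", mesh$id, "')")
  if (!all(is.finite(v)))
    stop("mesh '", mesh$id, "' has non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v)))
    stop("mesh '", mesh$id, "' has face indices outside 1..", nrow(v))
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("mesh '", mesh$id, "' has degenerate faces (repeated vertex index)")
  areas <- face_areas(mesh)
  tol <- 1e-14 * max(bbox_diagonal(mesh)^2, .Machine$double.xmin)
  if (any(areas <= tol))
    stop("mesh '", mesh$id, "' has zero-area faces")
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces%s\n", x$id,
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "" else ", normals cached"))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

face_normals_raw <- function(mesh) {
  # unnormalised face normals; length equals twice the face area, which is
  # exactly the area weighting wanted for vertex normals
  v <- mesh$vertices
  f <- mesh$faces
  cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
         v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
}

face_areas <- function(mesh) {
  fn <- face_normals_raw(mesh)
  0.5 * sqrt(rowSums(fn^2))
}

centroid <- function(mesh) colMeans(mesh$vertices)

bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Compute area-weighted per-vertex normals
#'
#' Each vertex normal is the normalised, area-weighted average of the normals
#' of its incident faces; orientation follows the face winding
#' (counter-clockwise seen from outside = outward).  Vertices with no
#' incident face get a zero normal and are flagged in the
#' `"isolated_vertices"` attribute; such vertices are exempted from
#' normal-compatibility tests during registration.
#'
#' @param mesh a `triangle_mesh`.
#' @return The mesh with its `normals` field filled (unit vectors, or zero
#'   rows for isolated vertices).
#' @export
compute_vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh)
  if (nrow(mesh$faces) < 1L) stop("mesh has no faces")
  fn <- face_normals_raw(mesh)
  nv <- nrow(mesh$vertices)
  g <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  acc <- rowsum(rbind(fn, fn, fn), group = g)
  nrm <- matrix(0, nv, 3)
  nrm[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(nrm^2))
  iso <- len < 1e-300
  nrm[!iso, ] <- nrm[!iso, , drop = FALSE] / len[!iso]
  mesh$normals <- nrm
  if (any(iso)) attr(mesh$normals, "isolated_vertices") <- which(iso)
  mesh
}

#' Watertightness check
#'
#' A closed orientable surface has every edge shared by exactly two faces and
#' Euler characteristic V - E + F = 2.
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` if the mesh is a closed manifold surface of genus 0.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (!all(tab == 2L)) return(FALSE)
  nV <- nrow(mesh$vertices)
  nE <- length(tab)
  nF <- nrow(f)
  (nV - nE + nF) == 2L
}

# Signed volume of a closed mesh; positive when faces wind counter-clockwise
# seen from outside (outward normals).
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c3))) / 6
}
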