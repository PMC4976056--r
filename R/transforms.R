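# Rigid transforms (rotation + translation) and mirror-imaging.

#' Rigid transform
#'
#' A proper rigid motion `v -> R v + t` with `R` a rotation (orthonormal,
#' det +1) and `t` a translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not a proper rotation matrix ",
         "(orthonormal with determinant +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation (mm): %.4f %.4f %.4f\n", x$translation[1],
              x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose(T1, T2)` is the transform that applies `T1` first, then `T2`.
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose <- function(t1, t2) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) +
                    t2$translation)
}

#' @rdname compose
#' @param transform a [rigid_transform()].
#' @export
inverse_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix of coordinates.
#' @param transform a [rigid_transform()].
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Apply a rigid transform to a mesh
#'
#' Vertices map as `v -> R v + t`; cached normals rotate as `n -> R n`.
#'
#' @param mesh a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @return The transformed mesh.
#' @export
apply_transform <- function(mesh, transform) {
  if (!inherits(transform, "rigid_transform"))
    stop("transform must be a rigid_transform")
  mesh$vertices <- transform_points(mesh$vertices, transform)
  if (!is.null(mesh$normals)) {
    iso <- attr(mesh$normals, "isolated_vertices")
    mesh$normals <- mesh$normals %*% t(transform$rotation)
    attr(mesh$normals, "isolated_vertices") <- iso
  }
  mesh
}

#' Mirror-image a mesh
#'
#' Reflects the coordinates across a coordinate plane through the origin
#' (default: the yz-plane, i.e. x-negation) and reverses the face winding so
#' that surface normals stay outward.  This is the preprocessing applied to
#' every right-side element before left-right comparison, mimicking the
#' mirror-imaging of right bones prior to registration.  The mirror plane is
#' irrelevant downstream (registration is invariant to rigid motion); a fixed
#' convention keeps outputs reproducible.
#'
#' @param mesh a [triangle_mesh()].
#' @param plane `"x"`, `"y"` or `"z"`: the coordinate negated.
#' @return The mirrored mesh, id suffixed `"_mirrored"`.
#' @export
mirror_mesh <- function(mesh, plane = c("x", "y", "z")) {
  plane <- match.arg(plane)
  ax <- match(plane, c("x", "y", "z"))
  mesh$vertices[, ax] <- -mesh$vertices[, ax]
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  if (!is.null(mesh$normals)) {
    iso <- attr(mesh$normals, "isolated_vertices")
    mesh$normals[, ax] <- -mesh$normals[, ax]
    attr(mesh$normals, "isolated_vertices") <- iso
  }
  mesh$id <- paste0(mesh$id, "_mirrored")
  mesh
}

#' Homogeneous-matrix representation
#'
#' @param transform a [rigid_transform()].
#' @return 4x4 homogeneous matrix.
#' @export
as_homogeneous <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname as_homogeneous
#' @param m 4x4 homogeneous matrix.
#' @export
from_homogeneous <- function(m) rigid_transform(m[1:3, 1:3], m[1:3, 4])

# Uniform random rotation (quaternion method); consumes 3 uniforms from the
# current RNG stream.
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_rot(q)
}

quat_to_rot <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Deterministic low-discrepancy rotations (Halton sequence bases 2/3/5
# mapped through the uniform-quaternion construction); used to fill the
# multi-start budget of the rough alignment.
halton_rotations <- function(n, skip = 0L) {
  halton1 <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  lapply(seq_len(n), function(k) {
    i <- k + skip
    u <- c(halton1(i, 2), halton1(i, 3), halton1(i, 5))
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    quat_to_rot(q)
  })
}
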