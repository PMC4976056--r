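# Mesh file input/output: Wavefront OBJ, ASCII/binary STL, ASCII PLY.
# STL stores three vertices per facet, so STL input is welded to a shared
# vertex set before any nearest-neighbour structure is built on it.

#' Read a triangle mesh from OBJ, STL or PLY
#'
#' Coordinates are taken verbatim as millimetres; no unit inference is done.
#' OBJ `vn` records are ignored on read (normals are recomputed from the
#' geometry).  STL facet-vertices are welded into a shared vertex set at a
#' tolerance of 1e-8 times the bounding-box diagonal.  PLY support covers
#' ASCII files with x/y/z vertex properties.
#'
#' @param path path to a `.obj`, `.stl` or `.ply` file.
#' @param id mesh label; defaults to the file name without extension.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, id = NULL) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  parsed <- switch(ext,
    obj = read_obj(path),
    stl = read_stl(path),
    ply = read_ply(path),
    stop("unsupported mesh format '.", ext, "' (expected .obj, .stl or .ply)")
  )
  if (nrow(parsed$faces) == 0L)
    stop("empty mesh (no faces) in ", path)
  if (!all(is.finite(parsed$vertices)))
    stop("format error in ", path, ": non-finite vertex coordinates")
  triangle_mesh(parsed$vertices, parsed$faces, id = id)
}

#' Write a triangle mesh
#'
#' Format chosen by file extension: `.obj` (v/f records), `.stl` (ASCII) or
#' `.ply` (ASCII).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format '.", ext, "'")
  )
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("format error in ", path, ": no vertices")
  vtok <- strsplit(trimws(sub("^v", "", vl)), "[[:space:]]+")
  v <- do.call(rbind, lapply(vtok, function(x) {
    suppressWarnings(as.numeric(x[1:3]))
  }))
  faces <- list()
  for (line in fl) {
    tok <- strsplit(trimws(sub("^f", "", line)), "[[:space:]]+")[[1]]
    idx <- suppressWarnings(as.integer(sub("/.*", "", tok)))
    if (anyNA(idx)) stop("format error in ", path, ": bad face record '",
                         line, "'")
    if (length(idx) < 3L) stop("format error in ", path,
                               ": face with <3 vertices")
    # fan-triangulate polygons
    for (k in seq_len(length(idx) - 2L))
      faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  f <- if (length(faces)) do.call(rbind, faces) else
    matrix(integer(0), 0, 3)
  list(vertices = v, faces = f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", mesh$id), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 count, 50 bytes per facet
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  binary <- length(count) == 1L && !is.na(count) && size == 84 + 50 * count
  if (binary) {
    tri <- matrix(0, count * 3L, 3)
    for (i in seq_len(count)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^[[:space:]]*vertex[[:space:]]", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("format error in ", path, ": malformed STL")
    tok <- strsplit(trimws(sub("vertex", "", vl)), "[[:space:]]+")
    tri <- do.call(rbind, lapply(tok, function(x)
      suppressWarnings(as.numeric(x[1:3]))))
  }
  if (!all(is.finite(tri)))
    stop("format error in ", path, ": non-finite vertex coordinates")
  f <- matrix(seq_len(nrow(tri)), ncol = 3, byrow = TRUE)
  diag_len <- sqrt(sum((apply(tri, 2, max) - apply(tri, 2, min))^2))
  weld_vertices(tri, f, tol = 1e-8 * max(diag_len, 1e-30))
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals_raw(mesh)
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$id), con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]),
                 con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid %s", mesh$id), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "ply")
    stop("format error in ", path, ": not a PLY file")
  if (!any(grepl("^format ascii", lines)))
    stop("only ASCII PLY is supported: ", path)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("format error in ", path, ": no end_header")
  header <- lines[seq_len(hend)]
  nv <- as.integer(sub(".*element vertex ", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face ", "",
                       grep("^element face", header, value = TRUE)[1]))
  vlines <- lines[(hend + 1):(hend + nv)]
  vtok <- strsplit(trimws(vlines), "[[:space:]]+")
  v <- do.call(rbind, lapply(vtok, function(x)
    suppressWarnings(as.numeric(x[1:3]))))
  flines <- lines[(hend + nv + 1):(hend + nv + nf)]
  ftok <- strsplit(trimws(flines), "[[:space:]]+")
  f <- do.call(rbind, lapply(ftok, function(x) {
    n <- as.integer(x[1])
    if (n != 3L) stop("format error in ", path, ": non-triangular PLY face")
    as.integer(x[2:4]) + 1L
  }))
  list(vertices = v, faces = f)
}

write_ply <- function(mesh, path, scalar = NULL, scalar_name = "quality",
                      label = NULL, label_name = "band") {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", mesh$id),
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(scalar))
    writeLines(sprintf("property float %s", scalar_name), con)
  if (!is.null(label))
    writeLines(sprintf("property int %s", label_name), con)
  writeLines(c(sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  vrec <- sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                  mesh$vertices[, 3])
  if (!is.null(scalar)) vrec <- paste(vrec, sprintf("%.9g", scalar))
  if (!is.null(label)) vrec <- paste(vrec, as.integer(label))
  writeLines(vrec, con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

#' Weld duplicated vertices
#'
#' Merges vertices closer than `tol` (coordinate-wise, by rounding onto a
#' grid of pitch `tol`) and remaps faces; faces that collapse under welding
#' are dropped.  Welding an already-welded mesh is a no-op.
#'
#' @param vertices,faces raw vertex/face arrays.
#' @param tol welding tolerance in mm.
#' @return list with welded `vertices` and `faces`.
#' @export
weld_vertices <- function(vertices, faces, tol) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- vertices[first, , drop = FALSE]
  f2 <- matrix(map[faces], ncol = 3)
  keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  list(vertices = v2, faces = f2[keep, , drop = FALSE])
}

#' Side-labelled collection of meshes
#'
#' @param side `"left"` or `"right"`.
#' @param meshes list of [triangle_mesh()] objects with unique ids.
#' @param manifest optional data frame mapping id to source path.
#' @return An object of class `specimen_set`.
#' @export
specimen_set <- function(side = c("left", "right"), meshes,
                         manifest = NULL) {
  side <- match.arg(side)
  ids <- vapply(meshes, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate mesh id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(ids)
  meshes <- meshes[ord]
  names(meshes) <- ids[ord]
  structure(list(side = side, meshes = meshes, manifest = manifest),
            class = "specimen_set")
}

#' @export
print.specimen_set <- function(x, ...) {
  cat(sprintf("specimen_set (%s): %d meshes\n", x$side, length(x$meshes)))
  cat(" ", paste(utils::head(names(x$meshes), 10), collapse = ", "),
      if (length(x$meshes) > 10) "...\n" else "\n")
  invisible(x)
}

#' @export
length.specimen_set <- function(x) length(x$meshes)

specimen_ids <- function(x) names(x$meshes)

#' Load a directory of side-labelled meshes
#'
#' The side of each file is inferred from an `_L` / `_R` suffix
#' (case-insensitive) immediately before the extension, unless a manifest
#' CSV with columns `id,path,side` overrides the convention.  Only meshes of
#' the requested side are loaded, in sorted-id order.
#'
#' @param dir directory containing `.obj`/`.stl`/`.ply` files.
#' @param side which side to load, `"left"` or `"right"`.
#' @param manifest optional path to a manifest CSV (`id,path,side`); relative
#'   paths are resolved against the manifest's directory.
#' @return A [specimen_set()].
#' @export
load_specimen_set <- function(dir, side = c("left", "right"),
                              manifest = NULL) {
  side <- match.arg(side)
  if (!is.null(manifest)) {
    if (!file.exists(manifest)) stop("manifest does not exist: ", manifest)
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("id", "path", "side")
    if (!all(need %in% names(man)))
      stop("manifest must have columns id,path,side")
    man <- man[tolower(man$side) == side, , drop = FALSE]
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                    file.path(dirname(manifest), man$path))
    ids <- man$id
  } else {
    if (!dir.exists(dir)) stop("directory does not exist: ", dir)
    files <- list.files(dir, pattern = "\\.(obj|stl|ply)$",
                        ignore.case = TRUE)
    if (length(files) == 0L) stop("no mesh files in ", dir)
    suffix <- if (side == "left") "_l" else "_r"
    keep <- grepl(paste0(suffix, "\\.[^.]*$"), tolower(files))
    files <- sort(files[keep])
    paths <- file.path(dir, files)
    ids <- sub("\\.[^.]*$", "", files)
  }
  if (anyDuplicated(ids))
    stop("duplicate id(s) in ", if (is.null(manifest)) dir else manifest,
         ": ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meshes <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    meshes[[i]] <- tryCatch(read_mesh(paths[i], id = ids[i]),
                            error = function(e)
                              stop("failed to read '", paths[i], "': ",
                                   conditionMessage(e), call. = FALSE))
  }
  specimen_set(side, meshes,
               manifest = data.frame(id = ids, path = paths,
                                     side = side,
                                     stringsAsFactors = FALSE))
}
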