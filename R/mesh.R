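#' Triangle mesh of a lesion patch
#'
#' Constructs the basic surface container used throughout the package: a set
#' of 3D vertices plus triangle connectivity. Coordinates are in millimetres
#' until [normalize_unit_square()] rescales the patch to a dimensionless unit
#' square.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param frame either `"raw"` (scanner/model units) or `"normalized"`
#'   (unit-square frame).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `frame`.
#' @export
triangle_mesh <- function(vertices, faces, frame = c("raw", "normalized")) {
  frame <- match.arg(frame)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(vertices) < 4L) stop("degenerate mesh: fewer than 4 vertices")
  if (nrow(faces) < 2L) stop("degenerate mesh: fewer than 2 faces")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range [1, ", nrow(vertices), "]")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    stop("face repeats a vertex")
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces, frame =", x$frame, "\n")
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  extent  x: [%.4g, %.4g]  y: [%.4g, %.4g]  z: [%.4g, %.4g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

# Merge vertices coincident within `tol` and drop faces that became
# degenerate (repeated vertex or zero area). Returns cleaned mesh; counts of
# merged vertices / dropped faces reported via message().
.clean_mesh <- function(vertices, faces, frame, tol = 1e-9) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  n_merged <- sum(!first)
  map <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3L)
  bad <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  # zero-area faces: cross product of the two edge vectors vanishes
  if (any(!bad)) {
    f <- faces[!bad, , drop = FALSE]
    e1 <- vertices[f[, 2], , drop = FALSE] - vertices[f[, 1], , drop = FALSE]
    e2 <- vertices[f[, 3], , drop = FALSE] - vertices[f[, 1], , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    zero <- sqrt(cx^2 + cy^2 + cz^2) <= .Machine$double.eps * 100
    bad[!bad][zero] <- TRUE
  }
  n_dropped <- sum(bad)
  faces <- faces[!bad, , drop = FALSE]
  if (n_merged > 0L || n_dropped > 0L)
    message("mesh cleaning: merged ", n_merged, " duplicate vertices, ",
            "dropped ", n_dropped, " degenerate faces")
  if (nrow(vertices) < 4L)
    stop("degenerate mesh: fewer than 4 vertices after cleaning")
  triangle_mesh(vertices, faces, frame)
}

#' Read a triangle mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (`v`/`f` records) and PLY (ascii and
#' binary_little_endian). Duplicate vertices within 1e-9 are merged and
#' zero-area faces dropped (reported via `message()`). A `frame` sidecar
#' comment written by [write_mesh()] is honoured; otherwise the mesh is
#' tagged `raw`.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"` or `"auto"` (by file extension).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obj = "obj", ply = "ply",
                     stop("cannot infer mesh format from extension '",
                          ext, "'"))
  }
  if (format == "obj") .read_obj(path) else .read_ply(path)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frame <- if (any(grepl("^# frame normalized", lines))) "normalized" else "raw"
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("not a parsable OBJ file: ", path)
  vt <- strsplit(trimws(sub("^v", "", vlines)), "[[:space:]]+")
  vertices <- t(vapply(vt, function(x) as.numeric(x[1:3]), numeric(3)))
  if (any(!is.finite(vertices))) stop("unparsable vertex record in ", path)
  ft <- strsplit(trimws(sub("^f", "", flines)), "[[:space:]]+")
  faces <- t(vapply(ft, function(x) {
    if (length(x) != 3L) stop("only triangular faces are supported")
    as.integer(sub("/.*$", "", x))
  }, integer(3)))
  if (any(is.na(faces)) || any(faces < 1L) || any(faces > nrow(vertices)))
    stop("OBJ face references vertex index outside 1..", nrow(vertices))
  .clean_mesh(vertices, faces, frame)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of PLY header in ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 500L) stop("not a parsable PLY file: ", path)
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format: ", fmt_line)
  frame <- if (any(grepl("^comment frame normalized", header)))
    "normalized" else "raw"

  # parse element/property declarations
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      p <- if (tok[2] == "list")
        list(list = TRUE, count_type = tok[3], type = tok[4], name = tok[5])
      else list(list = FALSE, type = tok[2], name = tok[3])
      elems[[cur]]$props <- c(elems[[cur]]$props, list(p))
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY file lacks vertex or face element: ", path)

  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar <- function(type) {
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", 1L, size = sizes[[type]], endian = "little")
    else
      readBin(con, "integer", 1L, size = sizes[[type]], endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  nv <- elems$vertex$count
  nf <- elems$face$count
  vprops <- elems$vertex$props
  vnames <- vapply(vprops, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% vnames))
    stop("PLY vertex element lacks x/y/z properties")

  if (binary) {
    vertices <- matrix(0, nv, 3L)
    for (i in seq_len(nv)) {
      for (p in vprops) {
        val <- read_scalar(p$type)
        j <- match(p$name, c("x", "y", "z"))
        if (!is.na(j)) vertices[i, j] <- val
      }
    }
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      for (p in elems$face$props) {
        if (p$list) {
          cnt <- read_scalar(p$count_type)
          idx <- integer(cnt)
          for (k in seq_len(cnt)) idx[k] <- read_scalar(p$type)
          if (p$name %in% c("vertex_indices", "vertex_index")) {
            if (cnt != 3L) stop("only triangular PLY faces are supported")
            faces[i, ] <- idx + 1L
          }
        } else {
          read_scalar(p$type)
        }
      }
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nv + nf) stop("truncated PLY body in ", path)
    vt <- strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+")
    ix <- match(c("x", "y", "z"), vnames)
    vertices <- t(vapply(vt, function(x) as.numeric(x[ix]), numeric(3)))
    ft <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
    faces <- t(vapply(ft, function(x) {
      cnt <- as.integer(x[1])
      if (cnt != 3L) stop("only triangular PLY faces are supported")
      as.integer(x[2:4]) + 1L
    }, integer(3)))
  }
  if (any(!is.finite(vertices))) stop("unparsable PLY vertex data in ", path)
  if (any(faces < 1L) || any(faces > nv))
    stop("PLY face references vertex index outside 0..", nv - 1L)
  .clean_mesh(vertices, faces, frame)
}

#' Write a triangle mesh to OBJ or PLY
#'
#' The normalization frame is preserved through a sidecar comment
#' (`# frame ...` in OBJ, `comment frame ...` in PLY) so that
#' `read_mesh(write_mesh(m))` round-trips the tag.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"obj"`, `"ply"` or `"auto"` (by extension). PLY is written
#'   as ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, obj = "obj", ply = "ply",
                     stop("cannot infer mesh format from extension '",
                          ext, "'"))
  }
  v <- mesh$vertices
  f <- mesh$faces
  lines <- if (format == "obj") {
    c(paste("# frame", mesh$frame),
      sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
      sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else {
    c("ply", "format ascii 1.0",
      paste("comment frame", mesh$frame),
      paste("element vertex", nrow(v)),
      "property double x", "property double y", "property double z",
      paste("element face", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header",
      sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  }
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write mesh to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Export per-vertex scalar values as a PLY property
#'
#' Writes the mesh with one extra float vertex property (default name
#' `quality`), e.g. the mean-curvature field, for visual inspection in a
#' mesh viewer.
#'
#' @param mesh a [triangle_mesh()].
#' @param values numeric vector, one value per vertex.
#' @param path output PLY path.
#' @param name property name.
#' @return `path`, invisibly.
#' @export
write_scalar_ply <- function(mesh, values, path, name = "quality") {
  stopifnot(inherits(mesh, "triangle_mesh"),
            length(values) == nrow(mesh$vertices))
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c("ply", "format ascii 1.0",
             paste("comment frame", mesh$frame),
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             paste("property float", name),
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header",
             sprintf("%.10g %.10g %.10g %.6g", v[, 1], v[, 2], v[, 3], values),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' Normalize a mesh to the unit square
#'
#' Translates the mesh so its centroid sits at the origin, then scales all
#' three axes by one common factor chosen so that the larger of the x- and
#' y-extents equals exactly 1. Uniform scaling keeps the patch's shape (all
#' pairwise-distance ratios) intact, which makes the fixed curvature-band
#' thresholds comparable across specimens of different physical size.
#'
#' @param mesh a [triangle_mesh()] with `frame = "raw"`.
#' @return a list with elements `mesh` (the normalized [triangle_mesh()]) and
#'   `record` (list with `scale_factor` and `translation`; raw coordinates
#'   are recovered as `v / scale_factor + translation`).
#' @export
normalize_unit_square <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (mesh$frame != "raw")
    stop("mesh is already in the normalized frame")
  v <- mesh$vertices
  centroid <- colMeans(v)
  v <- sweep(v, 2, centroid)
  ext_x <- diff(range(v[, 1]))
  ext_y <- diff(range(v[, 2]))
  m <- max(ext_x, ext_y)
  if (m <= .Machine$double.eps * 100)
    stop("degenerate extent: all vertices collinear along z")
  s <- 1 / m
  out <- triangle_mesh(v * s, mesh$faces, frame = "normalized")
  list(mesh = out,
       record = list(scale_factor = s, translation = centroid))
}
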