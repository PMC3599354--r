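#' Histogram / subsampling specification for shape descriptors
#'
#' Controls the inter-vertex distance histogram and the seeded subsampling
#' cap used when a curvature subset is large. The bin range is fixed in
#' normalized (unit-square) coordinates so histograms are comparable across
#' specimens.
#'
#' @param bin_count number of equally sized bins (default 40).
#' @param r_max upper end of the distance range (default 2, the largest
#'   distance reachable far inside a unit-square patch; larger distances are
#'   clipped into the last bin).
#' @param subsample_cap maximum number of points used for pairwise-distance
#'   computations; larger subsets are subsampled with `seed`.
#' @param seed integer seed for the subsampling draw.
#' @return list of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_count = 40L, r_max = 2.0,
                           subsample_cap = 2000L, seed = 1L) {
  stopifnot(bin_count >= 1L, r_max > 0, subsample_cap >= 2L)
  structure(list(bin_count = as.integer(bin_count), r_max = r_max,
                 subsample_cap = as.integer(subsample_cap),
                 seed = as.integer(seed)),
            class = "histogram_spec")
}

# evaluate expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# seeded subsample of rows used for all pairwise-distance work
.subsample_points <- function(points, spec) {
  n <- nrow(points)
  if (n <= spec$subsample_cap) return(points)
  keep <- .with_seed(spec$seed, sample.int(n, spec$subsample_cap))
  points[sort(keep), , drop = FALSE]
}

.pair_distances <- function(points) {
  if (is.null(points) || nrow(points) < 2L) return(numeric(0))
  as.numeric(dist(points))
}

#' Inter-vertex distance histogram (descriptors d0..d39)
#'
#' Counts all pairwise Euclidean distances of a curvature subset into
#' `bin_count` equal bins over `[0, r_max]`. Bins are half-open
#' `[k w, (k+1) w)` with the last bin closed; distances beyond `r_max` are
#' clipped into the last bin. Subsets larger than the subsample cap are
#' first reduced by a seeded uniform subsample.
#'
#' @param points numeric matrix of 3D points (one curvature subset).
#' @param spec a [histogram_spec()].
#' @return numeric vector of `bin_count` counts (all zero for fewer than two
#'   points).
#' @export
distance_histogram <- function(points, spec = histogram_spec()) {
  points <- .as_points(points)
  pts <- .subsample_points(points, spec)
  d <- .pair_distances(pts)
  nb <- spec$bin_count
  if (length(d) == 0L) return(numeric(nb))
  w <- spec$r_max / nb
  idx <- floor(d / w) + 1
  idx[idx > nb] <- nb            # clips d == r_max and anything beyond
  tabulate(idx, nbins = nb)
}

.as_points <- function(points) {
  if (is.null(points)) return(matrix(numeric(0), 0L, 3L))
  points <- as.matrix(points)
  if (ncol(points) != 3L && nrow(points) > 0L)
    stop("points must have 3 columns")
  points
}

#' Distance and frequency aspect ratios (d40, d41, d44) and vertex count (d45)
#'
#' @param points full subset point matrix (d45 counts these, before any
#'   subsampling).
#' @param histogram the 40-bin distance histogram of the subset.
#' @param spec the [histogram_spec()] used for the histogram (governs the
#'   subsample used for the distance ratios).
#' @return named numeric vector `c(d40, d41, d44, d45)`: max/mean distance,
#'   max/median distance, max/mean histogram frequency, vertex count. The
#'   three ratios are 0 when fewer than two points are present.
#' @export
scalar_descriptors <- function(points, histogram, spec = histogram_spec()) {
  points <- .as_points(points)
  n_true <- nrow(points)
  d <- .pair_distances(.subsample_points(points, spec))
  if (length(d) == 0L) {
    return(c(d40 = 0, d41 = 0, d44 = 0, d45 = n_true))
  }
  c(d40 = max(d) / mean(d),
    d41 = max(d) / median(d),
    d44 = max(histogram) / mean(histogram),
    d45 = n_true)
}

#' Convex-hull volume and surface area (d42, d43)
#'
#' 3D convex hull of a point set, computed by an incremental hull.
#' Degenerate inputs (fewer than four points, or collinear/coplanar sets)
#' yield volume 0 and surface 0 by contract.
#'
#' @param points numeric matrix of 3D points.
#' @return named numeric vector `c(d42, d43)` = (volume, surface area).
#' @export
convex_hull_measures <- function(points) {
  points <- .as_points(points)
  if (nrow(points) < 4L) return(c(d42 = 0, d43 = 0))
  h <- .convex_hull_3d(points)
  c(d42 = h[["volume"]], d43 = h[["surface"]])
}

#' Concentric-sphere occupancy counts (d46..d55)
#'
#' Counts subset points inside each of `sphere_count` concentric spheres
#' around the origin (the normalized mesh's centroid), with radii
#' `j * R / sphere_count`, `j = 1..sphere_count`, where `R` is the largest
#' vertex norm of the whole mesh. Counts are cumulative and non-decreasing;
#' the last count equals the subset size.
#'
#' @param points subset point matrix in the normalized frame.
#' @param R outer radius (max vertex norm over the whole mesh).
#' @param sphere_count number of spheres (default 10).
#' @return numeric vector of `sphere_count` counts.
#' @export
concentric_sphere_counts <- function(points, R, sphere_count = 10L) {
  points <- .as_points(points)
  if (nrow(points) == 0L) return(numeric(sphere_count))
  nr <- sqrt(rowSums(points^2))
  radii <- seq_len(sphere_count) * R / sphere_count
  vapply(radii, function(r) sum(nr <= r), 0)
}

#' Magnitude spectrum of a descriptor sequence
#'
#' Magnitudes of the discrete Fourier transform of the input, same length,
#' DC term first. Applied to the 40-bin distance histogram (d56..d95) and to
#' the 10-element sphere-count series (d96..d105).
#'
#' @param x numeric vector.
#' @return numeric vector `Mod(fft(x))` of the same length.
#' @export
fourier_magnitudes <- function(x) {
  Mod(fft(as.numeric(x)))
}

#' Hyperbolic-point count (d106)
#'
#' Number of subset vertices whose Gaussian curvature is negative (saddle
#' points).
#'
#' @param indices vertex indices of the subset.
#' @param field a `curvature_field` covering those indices.
#' @return integer count.
#' @export
count_hyperbolic <- function(indices, field) {
  stopifnot(inherits(field, "curvature_field"))
  sum(field$K[indices] < 0)
}

# all 107 descriptors of one curvature subset
.subset_descriptors <- function(points, R, n_hyperbolic,
                                spec = histogram_spec()) {
  points <- .as_points(points)
  nb <- spec$bin_count
  pts <- .subsample_points(points, spec)
  d <- .pair_distances(pts)
  if (length(d) == 0L) {
    hist <- numeric(nb)
    ratios <- c(0, 0, 0)
  } else {
    w <- spec$r_max / nb
    idx <- floor(d / w) + 1
    idx[idx > nb] <- nb
    hist <- tabulate(idx, nbins = nb)
    ratios <- c(max(d) / mean(d), max(d) / median(d),
                max(hist) / mean(hist))
  }
  hull <- convex_hull_measures(points)
  spheres <- concentric_sphere_counts(points, R)
  c(hist,                                   # d0  .. d39
    ratios[1], ratios[2],                   # d40, d41
    hull[[1]], hull[[2]],                   # d42, d43
    ratios[3],                              # d44
    nrow(points),                           # d45
    spheres,                                # d46 .. d55
    fourier_magnitudes(hist),               # d56 .. d95
    fourier_magnitudes(spheres),            # d96 .. d105
    n_hyperbolic)                           # d106
}

#' Assemble the 1284-element shape vector of a mesh
#'
#' Runs curvature estimation, partitions vertices into the curvature bands,
#' discards the flat band, and computes the 107 descriptors for each of the
#' 12 non-flat bands `S_0 .. S_11` in order. Empty bands contribute all-zero
#' blocks, so the vector length is always `12 * 107 = 1284`.
#'
#' @param mesh a [triangle_mesh()]; a raw-frame mesh is normalized to the
#'   unit square first.
#' @param spec a [histogram_spec()].
#' @param threshold_flat flat-band threshold passed to
#'   [partition_curvature()].
#' @param weighting curvature averaging weights, see [estimate_curvature()].
#' @return named numeric vector of length 1284 (names `s{n}_d{i}`), with
#'   attribute `subset_sizes` (the 12 band sizes).
#' @export
shape_vector <- function(mesh, spec = histogram_spec(),
                         threshold_flat = 0.17,
                         weighting = c("voronoi", "uniform")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  weighting <- match.arg(weighting)
  if (mesh$frame == "raw") mesh <- normalize_unit_square(mesh)$mesh
  field <- estimate_curvature(mesh, weighting = weighting)
  part <- partition_curvature(field, threshold_flat = threshold_flat)
  R <- max(sqrt(rowSums(mesh$vertices^2)))
  bands <- paste0("S_", 0:11)
  out <- numeric(0)
  sizes <- integer(12)
  for (b in seq_along(bands)) {
    idx <- part[[bands[b]]]
    sizes[b] <- length(idx)
    pts <- mesh$vertices[idx, , drop = FALSE]
    out <- c(out, .subset_descriptors(pts, R, count_hyperbolic(idx, field),
                                      spec))
  }
  names(out) <- shape_vector_names()
  attr(out, "subset_sizes") <- sizes
  out
}

#' Canonical shape-vector element names
#'
#' @return character vector of length 1284, `s{n}_d{i}` for band `n` in
#'   `0..11` and descriptor `i` in `0..106`.
#' @export
shape_vector_names <- function() {
  as.vector(t(outer(0:11, 0:106, function(n, i) sprintf("s%d_d%d", n, i))))
}

#' Featurize a list of meshes into a shape-vector matrix
#'
#' @param meshes list of [triangle_mesh()] objects.
#' @param spec a [histogram_spec()].
#' @param ... passed on to [shape_vector()].
#' @return numeric matrix, one row per mesh, 1284 named columns.
#' @export
featurize <- function(meshes, spec = histogram_spec(), ...) {
  out <- t(vapply(meshes, function(m) as.numeric(shape_vector(m, spec, ...)),
                  numeric(12L * 107L)))
  colnames(out) <- shape_vector_names()
  if (!is.null(names(meshes))) rownames(out) <- names(meshes)
  out
}

#' Write a shape-vector matrix as CSV
#'
#' One row per mesh: `mesh_id`, `label`, then the 1284 descriptor columns.
#'
#' @param x shape-vector matrix (rows = meshes).
#' @param labels class label per row.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shape_vectors <- function(x, labels, path) {
  df <- data.frame(mesh_id = if (is.null(rownames(x)))
    sprintf("mesh_%03d", seq_len(nrow(x))) else rownames(x),
    label = as.character(labels), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a shape-vector CSV written by [write_shape_vectors()]
#'
#' @param path CSV path.
#' @return list with `x` (matrix) and `labels` (factor).
#' @export
read_shape_vectors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$mesh_id
  list(x = x, labels = factor(df$label))
}
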