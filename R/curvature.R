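#' @useDynLib injuryshape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist fft median sd runif quantile
#' @importFrom utils head
NULL

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(a) sqrt(rowSums(a^2))

.normalize_rows <- function(a) {
  n <- .rownorm(a)
  n[n == 0] <- 1
  a / n
}

# Consistent-orientation check: every interior undirected edge must appear
# once in each direction across its two incident faces.
.check_orientation <- function(faces, n_vertices) {
  a <- c(faces[, 1], faces[, 2], faces[, 3])
  b <- c(faces[, 2], faces[, 3], faces[, 1])
  key_dir <- (a - 1) * as.double(n_vertices) + b
  if (anyDuplicated(key_dir))
    stop("orientation error: a directed edge occurs twice; ",
         "face normals are not globally consistent")
  lo <- pmin(a, b); hi <- pmax(a, b)
  key_und <- (lo - 1) * as.double(n_vertices) + hi
  mult <- table(key_und)
  if (any(mult > 2L))
    stop("orientation error: edge shared by more than two faces")
  boundary_key <- as.numeric(names(mult)[mult == 1L])
  # boundary vertices = endpoints of boundary edges
  lo_b <- floor((boundary_key - 1e-9) / n_vertices) + 1
  hi_b <- boundary_key - (lo_b - 1) * n_vertices
  sort(unique(c(lo_b, hi_b)))
}

# Mixed Voronoi area of each face corner (Meyer et al. convention):
# non-obtuse triangles get the true Voronoi split, obtuse triangles give
# half the area to the obtuse corner and a quarter to the others.
.corner_voronoi_areas <- function(v, f) {
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1; e23 <- p3 - p2
  area <- 0.5 * .rownorm(.cross3(e12, e13))
  l12 <- rowSums(e12^2); l13 <- rowSums(e13^2); l23 <- rowSums(e23^2)
  # cotangents at each corner: cot = dot / (2 * area)
  cot1 <- rowSums(e12 * e13) / (2 * area)
  cot2 <- rowSums(-e12 * e23) / (2 * area)
  cot3 <- rowSums(e13 * e23) / (2 * area)
  a1 <- (l13 * cot2 + l12 * cot3) / 8
  a2 <- (l12 * cot3 + l23 * cot1) / 8
  a3 <- (l23 * cot1 + l13 * cot2) / 8
  ob1 <- cot1 < 0; ob2 <- cot2 < 0; ob3 <- cot3 < 0
  obt <- ob1 | ob2 | ob3
  if (any(obt)) {
    a1[obt] <- area[obt] * ifelse(ob1[obt], 0.5, 0.25)
    a2[obt] <- area[obt] * ifelse(ob2[obt], 0.5, 0.25)
    a3[obt] <- area[obt] * ifelse(ob3[obt], 0.5, 0.25)
  }
  cbind(a1, a2, a3)
}

#' Estimate per-vertex curvature
#'
#' Estimates the second fundamental form (Weingarten matrix) of every face
#' from the variation of vertex normals along its edges (a least-squares fit
#' in the face's tangent frame), then averages the face tensors onto each
#' vertex after parallel transport into the vertex tangent plane. Principal
#' curvatures are the eigenvalues of the per-vertex tensor; mean curvature
#' `mc = (k1 + k2) / 2` is positive on locally convex regions, Gaussian
#' curvature `K = k1 * k2` is negative at hyperbolic (saddle) points.
#'
#' Face orientation must be globally consistent; otherwise an orientation
#' error is raised. Boundary vertices are retained: their estimates use only
#' the incident faces and they are flagged in the result.
#'
#' @param mesh a [triangle_mesh()] (normalized for pipeline use; any frame is
#'   accepted, curvature scales inversely with mesh size).
#' @param weighting `"voronoi"` (mixed Voronoi-area weights, default) or
#'   `"uniform"` for the face-to-vertex tensor averaging.
#' @return object of class `curvature_field`: list with per-vertex numeric
#'   vectors `mc`, `K`, `k1`, `k2` (with `k1 >= k2`), logical `hyperbolic`
#'   (`K < 0`), and logical `boundary`.
#' @export
estimate_curvature <- function(mesh, weighting = c("voronoi", "uniform")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  weighting <- match.arg(weighting)
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v); m <- nrow(f)

  boundary_idx <- .check_orientation(f, n)

  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  fn_raw <- .cross3(p2 - p1, p3 - p1)
  fn <- .normalize_rows(fn_raw)

  # area-weighted vertex normals
  vn <- matrix(0, n, 3L)
  for (c_ in 1:3) {
    idx <- f[, c_]
    vn[, 1] <- vn[, 1] + unname(tapply2(fn_raw[, 1], idx, n))
    vn[, 2] <- vn[, 2] + unname(tapply2(fn_raw[, 2], idx, n))
    vn[, 3] <- vn[, 3] + unname(tapply2(fn_raw[, 3], idx, n))
  }
  vn <- .normalize_rows(vn)

  # face tangent frame (u, w) orthonormal in the face plane
  u_f <- .normalize_rows(p2 - p1)
  w_f <- .cross3(fn, u_f)

  # least squares for the symmetric 2x2 form [e f; f g] from the 3 edges:
  # II %*% t(edge_uv) = t(dn_uv) for each edge
  edges <- list(list(a = 2L, b = 1L), list(a = 3L, b = 2L), list(a = 1L, b = 3L))
  Sxx <- Sxy <- Syy <- numeric(m)
  t1 <- t2 <- t3 <- numeric(m)
  for (ed in edges) {
    e <- v[f[, ed$a], , drop = FALSE] - v[f[, ed$b], , drop = FALSE]
    dn <- vn[f[, ed$a], , drop = FALSE] - vn[f[, ed$b], , drop = FALSE]
    x <- rowSums(e * u_f); y <- rowSums(e * w_f)
    a <- rowSums(dn * u_f); b <- rowSums(dn * w_f)
    Sxx <- Sxx + x * x; Sxy <- Sxy + x * y; Syy <- Syy + y * y
    t1 <- t1 + a * x
    t2 <- t2 + a * y + b * x
    t3 <- t3 + b * y
  }
  # normal equations, 3x3 per face, solved by Cramer's rule (vectorized)
  A11 <- Sxx; A12 <- Sxy; A13 <- rep(0, m)
  A22 <- Sxx + Syy; A23 <- Sxy; A33 <- Syy
  det3 <- A11 * (A22 * A33 - A23 * A23) - A12 * (A12 * A33) +
    A13 * (A12 * A23 - A22 * A13)
  det3[abs(det3) < .Machine$double.eps] <- NA
  ee <- (t1 * (A22 * A33 - A23 * A23) - A12 * (t2 * A33 - A23 * t3)) / det3
  ff <- (A11 * (t2 * A33 - A23 * t3) - t1 * (A12 * A33)) / det3
  gg <- (A11 * (A22 * t3 - t2 * A23) - A12 * (A12 * t3 - t2 * A13) +
           t1 * (A12 * A23 - A22 * A13)) / det3
  ee[is.na(ee)] <- 0; ff[is.na(ff)] <- 0; gg[is.na(gg)] <- 0

  # vertex tangent frames
  ref <- matrix(rep(c(1, 0, 0), each = n), n, 3L)
  alt <- abs(rowSums(vn * ref)) > 0.9
  ref[alt, ] <- matrix(rep(c(0, 1, 0), each = sum(alt)), ncol = 3L)
  u_v <- .normalize_rows(.cross3(vn, ref))
  w_v <- .cross3(vn, u_v)

  acc_e <- acc_f <- acc_g <- acc_w <- numeric(n)
  corner_w <- if (weighting == "voronoi") .corner_voronoi_areas(v, f)
  else matrix(1, m, 3L)

  for (c_ in 1:3) {
    vi <- f[, c_]
    nf_ <- fn
    nv_ <- vn[vi, , drop = FALSE]
    # rotate face frame about (nf x nv) so the face normal matches the
    # vertex normal (Rodrigues); degenerate when already aligned
    axis <- .cross3(nf_, nv_)
    s <- .rownorm(axis)
    cth <- rowSums(nf_ * nv_)
    k <- axis
    ok <- s > 1e-12
    k[ok, ] <- axis[ok, , drop = FALSE] / s[ok]
    rot <- function(x) {
      kxx <- .cross3(k, x)
      kdx <- rowSums(k * x)
      out <- x * cth + kxx * s + k * kdx * (1 - cth)
      out[!ok, ] <- x[!ok, , drop = FALSE]
      out
    }
    uf2 <- rot(u_f)
    wf2 <- rot(w_f)
    # vertex basis expressed in the transported face frame
    pu1 <- rowSums(u_v[vi, , drop = FALSE] * uf2)
    pu2 <- rowSums(u_v[vi, , drop = FALSE] * wf2)
    pv1 <- rowSums(w_v[vi, , drop = FALSE] * uf2)
    pv2 <- rowSums(w_v[vi, , drop = FALSE] * wf2)
    ce <- pu1 * (ee * pu1 + ff * pu2) + pu2 * (ff * pu1 + gg * pu2)
    cf <- pu1 * (ee * pv1 + ff * pv2) + pu2 * (ff * pv1 + gg * pv2)
    cg <- pv1 * (ee * pv1 + ff * pv2) + pv2 * (ff * pv1 + gg * pv2)
    wgt <- corner_w[, c_]
    acc_e <- acc_e + tapply2(ce * wgt, vi, n)
    acc_f <- acc_f + tapply2(cf * wgt, vi, n)
    acc_g <- acc_g + tapply2(cg * wgt, vi, n)
    acc_w <- acc_w + tapply2(wgt, vi, n)
  }
  acc_w[acc_w == 0] <- 1
  e_v <- acc_e / acc_w; f_v <- acc_f / acc_w; g_v <- acc_g / acc_w

  h <- (e_v + g_v) / 2
  disc <- sqrt(pmax((e_v - g_v)^2 / 4 + f_v^2, 0))
  k1 <- h + disc
  k2 <- h - disc
  K <- e_v * g_v - f_v^2
  boundary <- rep(FALSE, n)
  boundary[boundary_idx] <- TRUE
  structure(list(mc = h, K = K, k1 = k1, k2 = k2,
                 hyperbolic = K < 0, boundary = boundary),
            class = "curvature_field")
}

# fast grouped sum into a fixed-length vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.curvature_field <- function(x, ...) {
  cat("curvature_field:", length(x$mc), "vertices\n")
  cat(sprintf("  mc: [%.4g, %.4g]  hyperbolic: %d  boundary: %d\n",
              min(x$mc), max(x$mc), sum(x$hyperbolic), sum(x$boundary)))
  invisible(x)
}

#' Partition vertices into the 13 curvature bands
#'
#' Assigns every vertex to exactly one band by its mean curvature: a flat
#' band `S_f` with `|mc| <= threshold_flat` (discarded downstream), six
#' convex bands `S_0 .. S_5` and six concave bands `S_6 .. S_11`. Band
#' intervals are half-open as written above; at the flat threshold itself
#' the flat band wins.
#'
#' @param field a `curvature_field`.
#' @param threshold_flat flat-band half-width on `|mc|` (default 0.17, tuned
#'   for meshes in the unit-square frame).
#' @return object of class `curvature_partition`: a list of 13 integer
#'   vectors named `S_f`, `S_0` ... `S_11`, with attribute `threshold_flat`.
#' @export
partition_curvature <- function(field, threshold_flat = 0.17) {
  stopifnot(inherits(field, "curvature_field"))
  mc <- field$mc
  if (any(!is.finite(mc)))
    stop("non-finite mean curvature at vertex ",
         which(!is.finite(mc))[1])
  t <- threshold_flat
  bands <- list(
    S_f  = abs(mc) <= t,
    S_0  = mc > 0.8,
    S_1  = mc > 0.6  & mc <= 0.8,
    S_2  = mc > 0.5  & mc <= 0.6,
    S_3  = mc > 0.4  & mc <= 0.5,
    S_4  = mc > 0.25 & mc <= 0.4,
    S_5  = mc > t    & mc <= 0.25,
    S_6  = mc < -0.8,
    S_7  = mc >= -0.8  & mc < -0.6,
    S_8  = mc >= -0.6  & mc < -0.5,
    S_9  = mc >= -0.5  & mc < -0.4,
    S_10 = mc >= -0.4  & mc < -0.25,
    S_11 = mc >= -0.25 & mc < -t
  )
  out <- lapply(bands, which)
  structure(out, threshold_flat = t, n_vertices = length(mc),
            class = "curvature_partition")
}

#' @export
print.curvature_partition <- function(x, ...) {
  sizes <- vapply(x, length, 0L)
  cat("curvature_partition of", attr(x, "n_vertices"), "vertices",
      "(flat threshold", attr(x, "threshold_flat"), ")\n")
  print(sizes)
  invisible(x)
}
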