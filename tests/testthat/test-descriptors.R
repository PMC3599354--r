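test_that("distance histogram matches hand-enumerated examples", {
  spec <- histogram_spec()
  # three collinear points: distances {1, 1, 2}; width 0.05
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  h <- distance_histogram(pts, spec)
  expect_length(h, 40L)
  expected <- numeric(40)
  expected[21] <- 2   # bin index 20 (0-based): [1.00, 1.05)
  expected[40] <- 1   # distance 2 = r_max falls in the closed last bin
  expect_equal(h, expected)

  # single point: no pairs
  expect_equal(distance_histogram(rbind(c(1, 2, 3)), spec), numeric(40))

  # two points at distance 0.51 -> 0-based bin 10 only
  h2 <- distance_histogram(rbind(c(0, 0, 0), c(0.51, 0, 0)), spec)
  expect_equal(which(h2 != 0), 11L)
  expect_equal(sum(h2), 1)
})

test_that("aspect-ratio descriptors match hand arithmetic", {
  spec <- histogram_spec()
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  h <- distance_histogram(pts, spec)
  s <- scalar_descriptors(pts, h, spec)
  expect_equal(s[["d40"]], 2 / (4 / 3))   # max / mean of {1, 1, 2}
  expect_equal(s[["d41"]], 2 / 1)         # max / median
  expect_equal(s[["d44"]], 2 / (3 / 40))  # max freq / mean freq
  expect_equal(s[["d45"]], 3)

  # fewer than 2 points: ratios are 0 but the count is kept
  s1 <- scalar_descriptors(rbind(c(0, 0, 0)), numeric(40), spec)
  expect_equal(unname(s1), c(0, 0, 0, 1))
})

test_that("convex hull measures match closed-form solids", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_measures(cube), c(d42 = 1, d43 = 6))

  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  h <- convex_hull_measures(tet)
  expect_equal(h[["d42"]], 1 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_equal(h[["d43"]], sqrt(3), tolerance = 1e-12)

  # degenerate sets give (0, 0) by contract
  expect_equal(convex_hull_measures(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, 1))),
               c(d42 = 0, d43 = 0))
  copl <- cbind(runif(30), runif(30), 0.7)
  expect_equal(convex_hull_measures(copl), c(d42 = 0, d43 = 0))
})

test_that("hull of interior-padded solids ignores interior points", {
  set.seed(3)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  inner <- matrix(runif(90, 0.2, 0.8), ncol = 3)
  expect_equal(convex_hull_measures(rbind(cube, inner)), c(d42 = 1, d43 = 6))
  # icosphere vertices approximate the unit ball's volume and area
  sph <- icosphere(3)$vertices
  h <- convex_hull_measures(sph)
  expect_equal(h[["d42"]], 4 / 3 * pi, tolerance = 0.02)
  expect_equal(h[["d43"]], 4 * pi, tolerance = 0.02)
})

test_that("hulls of near-developable surface point sets stay well behaved", {
  # grid samples of a smooth groove are nearly coplanar in patches, the
  # hard case for incremental hulls; results must be finite and stable
  # under tiny jitter
  m <- deform_mesh(base_grid_mesh(60, 8), "smooth_strangulation", seed = 67)
  pts <- normalize_unit_square(m)$mesh$vertices
  h <- convex_hull_measures(pts)
  expect_true(all(is.finite(h)) && all(h >= 0))
  set.seed(1)
  h2 <- convex_hull_measures(pts + matrix(rnorm(length(pts), 0, 1e-9),
                                          nrow(pts)))
  expect_equal(h2, h, tolerance = 1e-5)
})

test_that("concentric-sphere counts are cumulative threshold counts", {
  R <- 2
  pts <- rbind(c(0.05 * R, 0, 0), c(0, 0.35 * R, 0), c(0, 0, 0.55 * R),
               c(0.95 * R, 0, 0))
  expect_equal(concentric_sphere_counts(pts, R),
               c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4))
  # all points at the origin fall inside the smallest sphere
  orig <- matrix(0, 5, 3)
  expect_equal(concentric_sphere_counts(orig, R), rep(5, 10))
  expect_equal(concentric_sphere_counts(orig[0, , drop = FALSE], R),
               numeric(10))
})

test_that("Fourier magnitudes match hand DFTs", {
  expect_equal(fourier_magnitudes(c(1, 1, 1, 1)), c(4, 0, 0, 0))
  expect_equal(fourier_magnitudes(c(1, 0, 0, 0)), c(1, 1, 1, 1))
  expect_equal(fourier_magnitudes(c(0, 1, 0, -1)), c(0, 2, 0, 2))
})

test_that("hyperbolic-point counts follow the sign of Gaussian curvature", {
  fc <- estimate_curvature(saddle_mesh(30))
  int <- which(!fc$boundary)
  expect_equal(count_hyperbolic(int, fc), length(int))
  sph <- estimate_curvature(icosphere(2))
  expect_equal(count_hyperbolic(seq_along(sph$mc), sph), 0)
  expect_equal(count_hyperbolic(integer(0), sph), 0)
})

test_that("shape vector has the fixed 12 x 107 block structure", {
  m <- deform_mesh(base_grid_mesh(50, 8), "textured_strangulation", seed = 2)
  sv <- shape_vector(m)
  expect_length(sv, 1284L)
  expect_equal(names(sv), shape_vector_names())
  expect_true(all(is.finite(sv)))
  sizes <- attr(sv, "subset_sizes")

  # per-band invariants: histogram mass, cumulative spheres, DC terms
  cap <- histogram_spec()$subsample_cap
  for (b in 0:11) {
    blk <- sv[sprintf("s%d_d%d", b, 0:106)]
    n_b <- sizes[b + 1]
    n_used <- min(n_b, cap)
    expect_equal(sum(blk[1:40]), choose(n_used, 2))
    expect_equal(blk[[46]], n_b)                       # d45 true size
    spheres <- blk[47:56]
    expect_true(all(diff(spheres) >= 0))
    if (n_b > 0) expect_equal(spheres[[10]], n_b)      # all within radius R
    expect_equal(blk[[57]], sum(blk[1:40]))            # DC of histogram
    expect_equal(blk[[97]], sum(spheres))              # DC of sphere series
  }
})

test_that("flat patches give the all-zero shape vector", {
  sv <- shape_vector(base_grid_mesh(30, 8))
  expect_equal(unname(sv), rep(0, 1284), ignore_attr = TRUE)
})

test_that("shape vectors are deterministic and rotation invariant", {
  m <- deform_mesh(base_grid_mesh(40, 8), "incised", seed = 5)
  sv1 <- shape_vector(m)
  sv2 <- shape_vector(m)
  expect_identical(sv1, sv2)

  # rotate the raw mesh about z before normalization (90 degrees keeps the
  # planar extents, so normalization is identical and every descriptor is
  # rotation invariant)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mr <- triangle_mesh(m$vertices %*% t(Rz), m$faces)
  svr <- shape_vector(mr)
  expect_equal(unname(svr), unname(sv1), tolerance = 1e-4)
})

test_that("subsampling caps pairwise work but keeps the true vertex count", {
  set.seed(8)
  pts <- matrix(rnorm(3000), ncol = 3)
  spec <- histogram_spec(subsample_cap = 200, seed = 4)
  h <- distance_histogram(pts, spec)
  expect_equal(sum(h), choose(200, 2))
  s <- scalar_descriptors(pts, h, spec)
  expect_equal(s[["d45"]], 1000)
  expect_identical(distance_histogram(pts, spec), h)  # seeded, reproducible
})

test_that("shape-vector CSV round-trips matrix and labels", {
  ds <- generate_injury_dataset(n_per_class = 2, resolution = 30, seed = 3)
  x <- featurize(ds$meshes)
  path <- withr::local_tempfile(fileext = ".csv")
  write_shape_vectors(x, ds$labels, path)
  back <- read_shape_vectors(path)
  expect_equal(unname(back$x), unname(x), tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(ds$labels))
})
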