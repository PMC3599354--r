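#' Canonical synthetic injury classes
#'
#' Returns the parameter specifications of the six modelled lesion
#' morphologies, each realized as a height-field deformation of a flat grid
#' patch (millimetre units):
#'
#' * `abrasion` — band-limited random roughness inside an irregular soft
#'   elliptical footprint (tangential graze, no straight edges).
#' * `incised` — a narrow straight V-groove, much longer than deep, with
#'   sharp wound edges.
#' * `gunshot` — a deep circular flat-bottomed pit with steep walls and a
#'   slight raised rim.
#' * `smooth_strangulation` — a wide smooth transverse U-groove crossing the
#'   whole patch.
#' * `textured_strangulation` — the same groove with periodic stria ridges
#'   along its valley.
#' * `patterned` — an L-shaped sharp-walled indentation with delineated
#'   straight edges.
#'
#' Depth/width parameters are in millimetres; each instance additionally
#' draws within-class jitter (position, rotation, depth and width
#' multipliers, roughness realization) from its seed.
#'
#' @return named list of class parameter lists.
#' @export
injury_classes <- function() {
  list(
    abrasion = list(amplitude = 0.25, corr_length = 0.8, footprint = 2.6,
                    aspect_jitter = c(0.7, 1.3)),
    incised = list(depth = 0.9, half_width = 0.35, length = 5.0),
    gunshot = list(depth = 1.3, radius = 0.9, rim_height = 0.12,
                   rim_width = 0.3),
    smooth_strangulation = list(depth = 0.7, width = 1.2),
    textured_strangulation = list(depth = 0.7, width = 1.2,
                                  stria_amplitude = 0.04,
                                  stria_period = 1.0),
    patterned = list(depth = 0.55, arm_width = 0.9, arm1_length = 3.2,
                     arm2_length = 2.2, edge_softness = 0.12)
  )
}

#' Flat evenly gridded base mesh
#'
#' An `n x n` height-field grid over a square patch with alternating
#' diagonal splits, so triangles are nearly equilateral in aspect. At the
#' default 80 vertices over 8 mm the resolution is about 10 vertices per
#' millimetre.
#'
#' @param resolution vertices per side (default 80, minimum 20).
#' @param side patch side length in mm (default 8).
#' @return a [triangle_mesh()] with `z = 0`, frame `raw`.
#' @export
base_grid_mesh <- function(resolution = 80L, side = 8) {
  n <- as.integer(resolution)
  stopifnot(n >= 4L)
  xs <- seq(0, side, length.out = n)
  v <- cbind(x = rep(xs, each = n), y = rep(xs, times = n), z = 0)
  # vertex index of grid node (i = y index, j = x index)
  id <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  a <- id(i, j); b <- id(i + 1L, j); c_ <- id(i, j + 1L); d <- id(i + 1L, j + 1L)
  alt <- (i + j) %% 2L == 0L
  # two CCW (+z) triangles per cell, diagonal direction alternating
  t1 <- cbind(a, c_, ifelse(alt, d, b))
  t2 <- cbind(ifelse(alt, a, c_), d, b)
  triangle_mesh(v, rbind(t1, t2), frame = "raw")
}

.soft_box <- function(t, a, b, s) {
  stats::plogis((t - a) / s) * stats::plogis((b - t) / s)
}

# band-limited roughness field on the n x n grid (sd ~ 1 inside the mask)
.roughness_field <- function(n, spacing, corr_length) {
  z <- matrix(stats::rnorm(n * n), n, n)
  xs <- (seq_len(n) - 1) * spacing
  kern <- exp(-outer(xs, xs, "-")^2 / (2 * corr_length^2))
  kern <- kern / rowSums(kern)
  sm <- kern %*% z %*% t(kern)
  sm / sd(as.numeric(sm))
}

#' Deform a flat grid mesh into one synthetic lesion instance
#'
#' Applies the class-characteristic height-field displacement with seeded
#' within-class jitter of position, rotation, depth and width. Height-field
#' deformation guarantees exactly one vertex per grid node (no folds or
#' self-intersections).
#'
#' @param mesh a flat grid mesh from [base_grid_mesh()].
#' @param class one of the names of [injury_classes()].
#' @param seed integer seed for the jitter draws.
#' @param params optional parameter list overriding the class defaults.
#' @return the deformed [triangle_mesh()] (frame `raw`).
#' @export
deform_mesh <- function(mesh, class, seed = 1L, params = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  specs <- injury_classes()
  if (!class %in% names(specs))
    stop("unknown injury class '", class, "'; expected one of: ",
         paste(names(specs), collapse = ", "))
  p <- utils::modifyList(specs[[class]], as.list(params))
  v <- mesh$vertices
  side_x <- diff(range(v[, 1]))
  n <- as.integer(round(sqrt(nrow(v))))

  h <- .with_seed(seed, {
    depth_mult <- runif(1, 0.55, 1.45)
    width_mult <- runif(1, 0.55, 1.45)
    cx <- mean(range(v[, 1])) + runif(1, -1.5, 1.5)
    cy <- mean(range(v[, 2])) + runif(1, -1.5, 1.5)
    theta <- runif(1, 0, 2 * pi)
    u <- cos(theta) * (v[, 1] - cx) + sin(theta) * (v[, 2] - cy)
    w <- -sin(theta) * (v[, 1] - cx) + cos(theta) * (v[, 2] - cy)

    switch(class,
      abrasion = {
        spacing <- side_x / (n - 1)
        rough <- .roughness_field(n, spacing,
                                  p$corr_length * runif(1, 0.7, 1.4))
        asp <- runif(1, p$aspect_jitter[1], p$aspect_jitter[2])
        rho2 <- (u / (p$footprint * width_mult * asp))^2 +
          (w / (p$footprint * width_mult / asp))^2
        amp <- p$amplitude * depth_mult
        amp * as.numeric(rough) * exp(-rho2)
      },
      incised = {
        d <- p$depth * depth_mult
        hw <- p$half_width * width_mult * runif(1, 0.8, 1.25)
        len <- p$length * runif(1, 0.55, 1.45)
        prof <- pmax(0, 1 - abs(w) / hw)
        env <- exp(-(2 * u / len)^8)
        -d * prof * env
      },
      gunshot = {
        d <- p$depth * depth_mult
        r0 <- p$radius * width_mult
        r <- sqrt(u^2 + w^2)
        pit <- -d * exp(-(r / r0)^4)
        rim <- p$rim_height * runif(1, 0.5, 1.5) *
          exp(-((r - 1.4 * r0) / p$rim_width)^2)
        pit + rim
      },
      smooth_strangulation = {
        d <- p$depth * depth_mult
        wd <- p$width * width_mult
        -d * exp(-(w / wd)^2)
      },
      textured_strangulation = {
        d <- p$depth * depth_mult
        wd <- p$width * width_mult
        phase <- runif(1, 0, 2 * pi)
        groove <- -d * exp(-(w / wd)^2)
        stria <- p$stria_amplitude * runif(1, 0.6, 1.4) *
          cos(2 * pi * u / (p$stria_period * runif(1, 0.8, 1.25)) + phase) *
          exp(-(w / wd)^2)
        groove + stria
      },
      patterned = {
        d <- p$depth * depth_mult
        aw <- p$arm_width * width_mult
        s <- p$edge_softness * runif(1, 0.8, 1.5)
        arm1 <- .soft_box(u, 0, p$arm1_length * runif(1, 0.7, 1.3), s) *
          .soft_box(w, -aw / 2, aw / 2, s)
        arm2 <- .soft_box(w, 0, p$arm2_length * runif(1, 0.7, 1.3), s) *
          .soft_box(u, -aw / 2, aw / 2, s)
        -d * pmax(arm1, arm2)
      })
  })
  v[, 3] <- v[, 3] + h
  triangle_mesh(v, mesh$faces, frame = "raw")
}

#' Generate a synthetic six-class lesion dataset
#'
#' Produces `n_per_class` deformed meshes for each injury class with child
#' seeds derived deterministically from the master seed, matching the study
#' design of 6 balanced classes of 18 specimens (108 meshes total) at the
#' defaults.
#'
#' @param n_per_class instances per class (default 18).
#' @param classes character vector of class names (default all six).
#' @param resolution grid vertices per side (default 80).
#' @param side patch side length in mm (default 8).
#' @param seed master seed.
#' @param sensor_noise amplitude of i.i.d. uniform vertex z-perturbation in
#'   mm emulating scanner noise (default 0).
#' @return object of class `injury_dataset`: list with `meshes` (named list
#'   of [triangle_mesh()]), `labels` (factor), `ids`, and the generation
#'   parameters.
#' @export
generate_injury_dataset <- function(n_per_class = 18L,
                                    classes = names(injury_classes()),
                                    resolution = 80L, side = 8,
                                    seed = 1L, sensor_noise = 0) {
  stopifnot(n_per_class >= 2L)
  base <- base_grid_mesh(resolution, side)
  total <- n_per_class * length(classes)
  child_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  meshes <- vector("list", total)
  labels <- character(total)
  ids <- character(total)
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      m <- deform_mesh(base, cl, seed = child_seeds[k])
      if (sensor_noise > 0) {
        z_noise <- .with_seed(child_seeds[k] %% 1000003L + 7L,
                              runif(nrow(m$vertices), -sensor_noise,
                                    sensor_noise))
        m$vertices[, 3] <- m$vertices[, 3] + z_noise
      }
      meshes[[k]] <- m
      labels[k] <- cl
      ids[k] <- sprintf("%s_%02d", cl, i)
    }
  }
  names(meshes) <- ids
  structure(list(meshes = meshes, labels = factor(labels, levels = classes),
                 ids = ids, seed = as.integer(seed),
                 resolution = as.integer(resolution), side = side,
                 sensor_noise = sensor_noise),
            class = "injury_dataset")
}

#' @export
print.injury_dataset <- function(x, ...) {
  cat("injury_dataset:", length(x$meshes), "meshes,",
      nlevels(x$labels), "classes, seed =", x$seed, "\n")
  print(table(x$labels))
  invisible(x)
}

#' Write a dataset's meshes and label table to disk
#'
#' @param dataset an `injury_dataset`.
#' @param dir output directory (created if missing).
#' @param format mesh format, `"obj"` or `"ply"`.
#' @return the label CSV path, invisibly.
#' @export
write_injury_dataset <- function(dataset, dir, format = c("obj", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in dataset$ids)
    write_mesh(dataset$meshes[[id]],
               file.path(dir, paste0(id, ".", format)), format)
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(mesh_id = dataset$ids,
                              class = as.character(dataset$labels)),
                   lab_path, row.names = FALSE)
  invisible(lab_path)
}
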