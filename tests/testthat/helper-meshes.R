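# Analytic test meshes built in code.

# unit icosphere by repeated subdivision of an icosahedron
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    key <- new.env()
    newf <- matrix(0L, 0, 3)
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(key[[k]])) return(key[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      key[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  triangle_mesh(v, f, frame = "normalized")
}

# open cylinder of radius r, outward normals
cylinder_mesh <- function(r = 0.5, nth = 60, nz = 30, height = 2) {
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  zs <- seq(0, height, length.out = nz)
  v <- cbind(r * cos(rep(th, nz)), r * sin(rep(th, nz)), rep(zs, each = nth))
  id <- function(i, j) (j - 1) * nth + i
  fs <- matrix(0L, 0, 3)
  for (j in 1:(nz - 1)) for (i in 1:nth) {
    i2 <- i %% nth + 1
    fs <- rbind(fs, c(id(i, j), id(i2, j), id(i2, j + 1)),
                c(id(i, j), id(i2, j + 1), id(i, j + 1)))
  }
  triangle_mesh(v, fs, frame = "normalized")
}

# grid sampling of z = x^2 - y^2 over [-1, 1]^2
saddle_mesh <- function(n = 40) {
  m <- base_grid_mesh(n, 2)
  v <- m$vertices
  v[, 1] <- v[, 1] - 1
  v[, 2] <- v[, 2] - 1
  v[, 3] <- v[, 1]^2 - v[, 2]^2
  triangle_mesh(v, m$faces, frame = "normalized")
}

# unit square split into two triangles
square_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

square_obj_text <- function() {
  c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "f 1 2 3", "f 1 3 4")
}

# small six-class descriptor matrix with known structure: one perfectly
# separating column per class plus iid noise columns
toy_class_matrix <- function(n_per_class = 6, n_noise = 20, gap = 50,
                             seed = 99) {
  classes <- paste0("c", 1:6)
  labels <- factor(rep(classes, each = n_per_class), levels = classes)
  n <- length(labels)
  set.seed(seed)
  signal <- vapply(1:6, function(k)
    ifelse(labels == classes[k], gap, 0) + rnorm(n), numeric(n))
  noise <- matrix(rnorm(n * n_noise), n)
  x <- cbind(signal, noise)
  colnames(x) <- c(paste0("sig", 1:6), paste0("noise", seq_len(n_noise)))
  list(x = x, labels = labels)
}
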