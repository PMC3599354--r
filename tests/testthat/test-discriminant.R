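toy_gaussians <- function(n = 30, p = 4, sep = 6, K = 3, seed = 42) {
  set.seed(seed)
  labels <- factor(rep(paste0("g", 1:K), each = n))
  mu <- matrix(0, K, p)
  for (k in 1:K) mu[k, ((k - 1) %% p) + 1] <- sep * k
  x <- do.call(rbind, lapply(1:K, function(k)
    sweep(matrix(rnorm(n * p), n, p), 2, mu[k, ], "+")))
  # mildly correlated features so LDA is non-trivial
  A <- diag(p) + 0.2
  list(x = x %*% A, labels = labels)
}

test_that("standardization centers, scales, and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  s <- standardize(x)
  expect_equal(colMeans(s$x), c(a = 0, b = 0))
  expect_equal(apply(s$x, 2, sd), c(a = 1, b = 1))
  # a test value equal to the training mean maps to 0
  t2 <- standardize(rbind(c(2, 30)), stats = s)
  expect_equal(unname(t2$x), rbind(c(0, 0)))
  # restandardizing with its own statistics is the identity
  s2 <- standardize(s$x, stats = list(center = c(0, 0), scale = c(1, 1)))
  expect_equal(s2$x, s$x, tolerance = 1e-12)
  expect_error(standardize(cbind(a = c(1, 1, 1))), "zero-variance")
})

test_that("lambda = 1, gamma = 0 reproduces an independent LDA", {
  skip_if_not_installed("MASS")
  toy <- toy_gaussians()
  fit <- shape_rda(toy$x, toy$labels, lambda = 1, gamma = 0)
  # all shrunken covariances collapse onto the pooled covariance
  expect_equal(fit$cov[[1]], fit$cov[[2]], tolerance = 1e-12)
  expect_equal(fit$cov[[1]], fit$cov[[3]], tolerance = 1e-12)
  pred <- predict(fit, toy$x)$class
  lda <- MASS::lda(toy$x, toy$labels)
  pred_lda <- predict(lda, toy$x)$class
  expect_equal(as.character(pred), as.character(pred_lda))
})

test_that("shrinkage limit cases match the covariance formulas", {
  toy <- toy_gaussians(n = 40)
  # lambda = 0, gamma = 0: per-class sample covariance of standardized data
  fit0 <- shape_rda(toy$x, toy$labels, lambda = 0, gamma = 0)
  xs <- standardize(toy$x)$x
  S1 <- cov(xs[toy$labels == "g1", ])
  expect_equal(unname(fit0$cov[[1]]), unname(S1), tolerance = 1e-12)
  # gamma = 1: exactly spherical with the trace preserved on average
  fit1 <- shape_rda(toy$x, toy$labels, lambda = 0.5, gamma = 1)
  for (S in fit1$cov) {
    expect_equal(unname(S), diag(S[1, 1], ncol(toy$x)), tolerance = 1e-12)
  }
})

test_that("increasing gamma drives covariances toward sphericity", {
  toy <- toy_gaussians(n = 40)
  conds <- vapply(c(0, 0.1, 0.5, 1), function(g) {
    fit <- shape_rda(toy$x, toy$labels, lambda = 0.3, gamma = g)
    max(summary(fit)$condition_numbers)
  }, 0)
  expect_true(all(diff(conds) <= 1e-9))
  expect_equal(conds[4], 1, tolerance = 1e-9)
})

test_that("fitted covariances are symmetric positive definite", {
  toy <- toy_gaussians()
  fit <- shape_rda(toy$x, toy$labels, lambda = 0.99, gamma = 0.001)
  for (S in fit$cov) {
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("singular covariances raise an error advising larger gamma", {
  # more features than per-class samples makes pure QDA infeasible
  set.seed(2)
  x <- matrix(rnorm(12 * 20), 12, 20)
  labels <- factor(rep(c("a", "b"), each = 6))
  expect_error(shape_rda(x, labels, lambda = 0, gamma = 0, scale = FALSE),
               "singular")
  expect_silent(fit <- shape_rda(x, labels, lambda = 0, gamma = 0.5,
                                 scale = FALSE))
})

test_that("classification picks the nearest class under equal covariances", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0, 1), 20, 2),
             sweep(matrix(rnorm(40, 0, 1), 20, 2), 2, c(10, 0), "+"))
  labels <- factor(rep(c("a", "b"), each = 20))
  fit <- shape_rda(x, labels, lambda = 1, gamma = 0)
  pred <- predict(fit, rbind(c(1, 0), c(9, 0)))
  expect_equal(as.character(pred$class), c("a", "b"))
  # x at a class mean is assigned to that class
  mu_b <- colMeans(x[labels == "b", ])
  expect_equal(as.character(predict(fit, rbind(mu_b))$class), "b")
  # adding a constant to all scores of a sample cannot change the argmin
  sc <- pred$scores
  expect_equal(apply(sc, 1, which.min), apply(sc + 5, 1, which.min))
})

test_that("training CRR is perfect for widely separated spherical classes", {
  toy <- toy_gaussians(n = 25, sep = 8)
  fit <- shape_rda(toy$x, toy$labels)
  expect_equal(mean(predict(fit, toy$x)$class == toy$labels), 1.0)
})

test_that("Mahalanobis distances reduce to known closed forms", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 5), 30, 2))
  labels <- factor(rep(c("a", "b"), each = 30))
  fit <- shape_rda(x, labels, lambda = 1, gamma = 1, scale = FALSE)
  # gamma = 1 makes Sigma = c I, so d = euclidean / sqrt(c)
  d <- mahalanobis_distances(fit, x)
  mu_a <- fit$means["a", ]
  c_ <- fit$cov[["a"]][1, 1]
  eu <- sqrt(colSums((t(x) - mu_a)^2))
  expect_equal(unname(d[, "a"]), unname(eu / sqrt(c_)), tolerance = 1e-9)
  # distance to the own class mean is zero
  expect_equal(mahalanobis_distances(fit, rbind(mu_a))[1, "a"], c(a = 0))
  # within-class distances are smaller than between-class on separated data
  expect_lt(mean(d[labels == "a", "a"]), mean(d[labels == "a", "b"]))
})

test_that("one-vs-rest AUC matches the rank formula limits and pROC", {
  labels <- factor(c("a", "a", "a", "b", "b", "b"), levels = c("a", "b"))
  sep <- cbind(a = c(1, 2, 3, 9, 8, 7), b = c(9, 8, 7, 1, 2, 3))
  expect_equal(roc_auc_ovr(sep, labels), c(a = 1, b = 1))
  ties <- cbind(a = rep(1, 6), b = rep(1, 6))
  expect_equal(roc_auc_ovr(ties, labels), c(a = 0.5, b = 0.5))
  inv <- cbind(a = c(9, 8, 7, 1, 2, 3), b = c(1, 2, 3, 9, 8, 7))
  expect_equal(roc_auc_ovr(inv, labels), c(a = 0, b = 0))

  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- cbind(a = rnorm(40), b = rnorm(40))
  lab <- factor(sample(c("a", "b"), 40, TRUE), levels = c("a", "b"))
  mine <- roc_auc_ovr(sc, lab)[["a"]]
  ref <- as.numeric(pROC::auc(pROC::roc(lab == "a", -sc[, "a"],
                                        quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)

  expect_error(roc_auc_ovr(sep, factor(rep("a", 6), levels = c("a", "b"))),
               "undefined AUC")
})

test_that("the shrinkage grid search ranks parameter pairs by training CRR", {
  toy <- toy_gaussians(n = 15)
  grid <- rda_grid_search(toy$x, toy$labels, lambdas = c(0.5, 1),
                          gammas = c(0.001, 1))
  expect_equal(nrow(grid), 4L)
  expect_true(all(grid$crr >= 0 & grid$crr <= 1, na.rm = TRUE))
  expect_false(is.unsorted(rev(grid$crr), na.rm = TRUE))
})
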