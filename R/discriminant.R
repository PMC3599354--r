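#' Standardize descriptor columns
#'
#' Centers and scales columns to mean 0 / sd 1 using training statistics.
#' When `stats` is supplied (from a previous training call), those statistics
#' are applied unchanged — test data must never contribute to them.
#'
#' @param x samples x descriptors matrix.
#' @param stats optional list with `center` and `scale` from a training call.
#' @return list with `x` (transformed matrix), `center`, `scale`.
#' @export
standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    if (any(scale == 0)) {
      bad <- which(scale == 0)
      nm <- if (!is.null(colnames(x))) colnames(x)[bad] else bad
      stop("zero-variance training column(s): ",
           paste(utils::head(nm, 5L), collapse = ", "),
           " (should have been removed by descriptor selection)")
    }
  } else {
    if (length(stats$center) != ncol(x))
      stop("standardization statistics do not match the descriptor set")
    center <- stats$center
    scale <- stats$scale
  }
  out <- sweep(sweep(x, 2, center), 2, scale, "/")
  list(x = out, center = center, scale = scale)
}

#' Regularized discriminant analysis with double covariance shrinkage
#'
#' Fits a Gaussian discriminant classifier whose per-class covariances are
#' shrunk twice: first toward the pooled covariance,
#' `S_k(lambda) = (1 - lambda) S_k + lambda S`, then toward a scaled
#' identity, `S_k(lambda, gamma) = (1 - gamma) S_k(lambda) +
#' gamma (tr(S_k(lambda)) / p) I`. `lambda = 1, gamma = 0` recovers linear
#' discriminant analysis; `lambda = gamma = 0` recovers quadratic
#' discriminant analysis (feasible only when every class covariance is
#' nonsingular).
#'
#' Columns are standardized internally to mean 0 / sd 1 on the training
#' data; the statistics are stored and re-applied by [predict.shape_rda()].
#'
#' @param x training matrix, samples in rows.
#' @param grouping class label per row (coerced to factor).
#' @param lambda shrinkage toward the pooled covariance, in `[0, 1]`
#'   (default 0.99).
#' @param gamma shrinkage toward the scaled identity, in `[0, 1]`
#'   (default 0.001).
#' @param prior per-class prior probabilities (default uniform).
#' @param scale standardize internally (default `TRUE`; set `FALSE` if `x`
#'   is already standardized and no rescaling of new data is wanted).
#' @param features optional integer/character vector naming the columns to
#'   use (e.g. the `kept` set of a `selection_report`).
#' @return object of class `shape_rda`: class means, shrunken covariances
#'   (with Cholesky factors and log-determinants), priors, standardization
#'   statistics and the feature list.
#' @export
shape_rda <- function(x, grouping, lambda = 0.99, gamma = 0.001,
                      prior = NULL, scale = TRUE, features = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, gamma >= 0, gamma <= 1)
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  grouping <- factor(grouping)
  cls <- levels(grouping)
  K <- length(cls)
  counts <- table(grouping)
  if (any(counts < 2L))
    stop("every class needs at least 2 training samples")
  if (is.null(prior)) prior <- rep(1 / K, K)
  if (abs(sum(prior) - 1) > 1e-12 || any(prior < 0))
    stop("priors must be non-negative and sum to 1")
  names(prior) <- cls

  std <- if (scale) standardize(x)
  else list(x = x, center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- std$x
  p <- ncol(xs)
  n <- nrow(xs)

  means <- do.call(rbind, lapply(cls, function(g)
    colMeans(xs[grouping == g, , drop = FALSE])))
  rownames(means) <- cls
  S_list <- lapply(cls, function(g) stats::cov(xs[grouping == g, , drop = FALSE]))
  names(S_list) <- cls
  pooled <- Reduce(`+`, Map(function(S, nk) S * (nk - 1), S_list,
                            as.list(as.numeric(counts)))) / (n - K)

  cov_k <- list(); chol_k <- list(); logdet <- numeric(K)
  for (i in seq_len(K)) {
    Sl <- (1 - lambda) * S_list[[i]] + lambda * pooled
    Sg <- (1 - gamma) * Sl + gamma * (sum(diag(Sl)) / p) * diag(p)
    Sg <- (Sg + t(Sg)) / 2
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch))
      stop("class covariance for '", cls[i], "' is singular at lambda = ",
           lambda, ", gamma = ", gamma,
           "; increase gamma (pure QDA is typically infeasible here)")
    cov_k[[i]] <- Sg
    chol_k[[i]] <- ch
    logdet[i] <- 2 * sum(log(diag(ch)))
  }
  names(cov_k) <- names(chol_k) <- cls
  names(logdet) <- cls

  structure(list(lambda = lambda, gamma = gamma, prior = prior,
                 classes = cls, means = means, cov = cov_k,
                 chol = chol_k, logdet = logdet,
                 center = std$center, scale = std$scale,
                 scaled = scale, features = features,
                 counts = as.integer(counts), p = p, n = n),
            class = "shape_rda")
}

#' @export
print.shape_rda <- function(x, ...) {
  cat("Regularized discriminant analysis (shape_rda)\n")
  cat(sprintf("  lambda = %g (toward pooled), gamma = %g (toward identity)\n",
              x$lambda, x$gamma))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  %d features, %d training samples\n", x$p, x$n))
  invisible(x)
}

#' @export
summary.shape_rda <- function(object, ...) {
  cond <- vapply(object$cov, function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    max(ev) / min(ev)
  }, 0)
  out <- list(model = object, condition_numbers = cond,
              logdet = object$logdet, prior = object$prior)
  class(out) <- "summary.shape_rda"
  out
}

#' @export
print.summary.shape_rda <- function(x, ...) {
  print(x$model)
  cat("  covariance condition numbers:\n")
  print(signif(x$condition_numbers, 4))
  invisible(x)
}

# quadratic form (x - mu)' Sigma^-1 (x - mu) for all rows, via Cholesky
.qform <- function(x, mu, ch) {
  d <- sweep(x, 2, mu)
  z <- backsolve(ch, t(d), transpose = TRUE)
  colSums(z^2)
}

#' Classify samples with a fitted RDA model
#'
#' Computes the per-class discriminant score
#' `ds_k(x) = (x - mu_k)' Sigma_k^-1 (x - mu_k) + log det Sigma_k -
#' 2 log prior_k` and assigns each sample to the class minimizing it. Ties
#' go to the lowest class index.
#'
#' @param object a [shape_rda()] model.
#' @param newdata matrix of samples on the original (unstandardized) scale
#'   and the same descriptor set used at fit time.
#' @param ... unused.
#' @return list with `class` (factor of predictions), `scores`
#'   (samples x classes matrix of `ds`), and `posterior` (softmax weights
#'   `exp(-ds/2)` normalized per sample).
#' @export
predict.shape_rda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!is.null(colnames(x)) &&
        all(as.character(object$features) %in% colnames(x)))
      x <- x[, object$features, drop = FALSE]
    else if (ncol(x) != object$p)
      x <- x[, object$features, drop = FALSE]
  }
  if (ncol(x) != object$p)
    stop("newdata has ", ncol(x), " features; model expects ", object$p)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  K <- length(object$classes)
  scores <- matrix(0, nrow(xs), K, dimnames = list(NULL, object$classes))
  for (i in seq_len(K)) {
    scores[, i] <- .qform(xs, object$means[i, ], object$chol[[i]]) +
      object$logdet[i] - 2 * log(object$prior[i])
  }
  idx <- apply(scores, 1, which.min)   # ties -> lowest class index
  w <- exp(-(scores - apply(scores, 1, min)) / 2)
  w <- w / rowSums(w)
  list(class = factor(object$classes[idx], levels = object$classes),
       scores = scores, posterior = w)
}

#' Mahalanobis distances to each class
#'
#' `d_k(x) = sqrt((x - mu_k)' Sigma_k^-1 (x - mu_k))` per sample and class,
#' using the model's shrunken class covariances.
#'
#' @param model a [shape_rda()] model.
#' @param x matrix of samples (original scale, model's descriptor set).
#' @return samples x classes numeric matrix.
#' @export
mahalanobis_distances <- function(model, x) {
  stopifnot(inherits(model, "shape_rda"))
  x <- as.matrix(x)
  if (!is.null(model$features) && ncol(x) != model$p)
    x <- x[, model$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  out <- vapply(seq_along(model$classes), function(i)
    sqrt(.qform(xs, model$means[i, ], model$chol[[i]])),
    numeric(nrow(xs)))
  out <- matrix(out, nrow = nrow(xs),
                dimnames = list(NULL, model$classes))
  out
}

#' One-vs-rest ROC AUC from discriminant scores
#'
#' For each class, uses the negated discriminant score as the
#' class-membership score and computes the area under the ROC curve against
#' the one-vs-rest truth by the rank (Mann-Whitney) formula with midrank
#' tie handling.
#'
#' @param scores samples x classes matrix of discriminant scores (lower =
#'   more class-like), e.g. `predict(model, x)$scores`.
#' @param labels true class per sample.
#' @return named numeric vector of per-class AUCs.
#' @export
roc_auc_ovr <- function(scores, labels) {
  labels <- factor(labels, levels = colnames(scores))
  if (anyNA(labels))
    stop("labels contain classes not present in the score matrix")
  vapply(colnames(scores), function(cl) {
    pos <- labels == cl
    if (!any(pos) || all(pos))
      stop("undefined AUC: class '", cl, "' has no positives or no negatives")
    s <- -scores[, cl]
    r <- rank(s)                      # midranks for ties
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
}

#' Grid search over RDA shrinkage parameters
#'
#' Scores each (lambda, gamma) combination by the training-set correct
#' recognition rate, mirroring a crude descriptive parameter sweep.
#' Combinations where a class covariance is singular get `NA`.
#'
#' @param x training matrix.
#' @param labels class labels.
#' @param lambdas,gammas parameter grids.
#' @return data frame with columns `lambda`, `gamma`, `crr`, sorted by
#'   decreasing `crr`.
#' @export
rda_grid_search <- function(x, labels,
                            lambdas = c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1),
                            gammas = c(0, 0.001, 0.01, 0.1, 1)) {
  grid <- expand.grid(lambda = lambdas, gamma = gammas)
  grid$crr <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- tryCatch(shape_rda(x, labels, lambda = grid$lambda[i],
                              gamma = grid$gamma[i]),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    mean(predict(fit, x)$class == factor(labels))
  }, 0)
  grid[order(-grid$crr), ]
}
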