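#' Stratified k-fold plan
#'
#' Shuffles samples within each class (seeded) and deals them round-robin
#' into `k` folds, so every test fold holds exactly `class size / k` samples
#' of each class. With 108 samples in 6 classes of 18 and `k = 6`, each fold
#' tests 18 samples (3 per class) against 90 training samples.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 6).
#' @param seed integer seed for the within-class shuffle.
#' @return object of class `fold_plan`: list with `k`, `test_sets` (list of
#'   index vectors), `seed`, `labels`.
#' @export
make_stratified_folds <- function(labels, k = 6L, seed = 1L) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts %% k != 0))
    stop("stratification error: class size(s) ",
         paste(names(counts)[counts %% k != 0], collapse = ", "),
         " not divisible by k = ", k)
  assignment <- integer(length(labels))
  .with_seed(seed, {
    for (g in levels(labels)) {
      idx <- which(labels == g)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  test_sets <- lapply(seq_len(k), function(f) which(assignment == f))
  structure(list(k = as.integer(k), test_sets = test_sets,
                 seed = as.integer(seed), labels = labels),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan: k =", x$k, ", seed =", x$seed, "\n")
  sizes <- vapply(x$test_sets, length, 0L)
  cat("  test-fold sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Cross-validated classification with per-fold descriptor selection
#'
#' For each fold, runs the full protocol on the training rows only:
#' descriptor selection (SNR, moment, correlation filters), standardization
#' statistics, and the RDA fit; then classifies the held-out test rows and
#' counts misclassifications. Selection and standardization never see test
#' rows. The mean CRR is the unweighted average of per-fold CRRs.
#'
#' @param x samples x descriptors matrix (full shape-vector matrix).
#' @param labels class labels.
#' @param plan a [make_stratified_folds()] plan.
#' @param thresholds a [selection_thresholds()].
#' @param lambda,gamma RDA shrinkage parameters (defaults 0.99 / 0.001).
#' @param on_empty what to do when no descriptor survives the filter cascade
#'   in a fold: `"error"` (default) propagates the empty-selection error
#'   tagged with the fold id; `"top"` falls back to the `n_top` descriptors
#'   with the highest pairwise SNR (recorded in the fold's report). The
#'   fallback keeps heavy-noise experiments defined.
#' @param n_top fallback size for `on_empty = "top"`.
#' @return object of class `shape_cv`: per-fold misclassification counts and
#'   CRRs, `mean_crr`, per-fold `selection_report`s, a pooled confusion
#'   matrix, and per-sample predictions.
#' @export
run_cross_validation <- function(x, labels, plan,
                                 thresholds = selection_thresholds(),
                                 lambda = 0.99, gamma = 0.001,
                                 on_empty = c("error", "top"),
                                 n_top = 10L) {
  on_empty <- match.arg(on_empty)
  x <- as.matrix(x)
  labels <- factor(labels)
  stopifnot(length(labels) == nrow(x))
  k <- plan$k
  cls <- levels(labels)
  confusion <- matrix(0L, length(cls), length(cls),
                      dimnames = list(truth = cls, predicted = cls))
  errors <- integer(k)
  crr <- numeric(k)
  reports <- vector("list", k)
  predicted <- factor(rep(NA_character_, nrow(x)), levels = cls)

  for (f in seq_len(k)) {
    test_idx <- plan$test_sets[[f]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    xtr <- x[train_idx, , drop = FALSE]
    ytr <- labels[train_idx]
    rep_f <- tryCatch(
      select_descriptors(xtr, ytr, thresholds),
      injuryshape_empty_selection = function(e) {
        if (on_empty == "error")
          stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
        snr <- pairwise_snr(xtr, ytr)
        kept <- order(-snr, seq_along(snr))[seq_len(min(n_top, length(snr)))]
        structure(list(kept = sort(kept), snr = snr,
                       moments = NULL,
                       dropped = list(snr = setdiff(seq_along(snr), kept),
                                      moments = integer(0),
                                      correlation = integer(0)),
                       correlation_pairs = NULL,
                       thresholds = thresholds,
                       filter_order = "top-snr fallback",
                       fallback = TRUE),
                  class = "selection_report")
      })
    reports[[f]] <- rep_f
    fit <- tryCatch(
      shape_rda(xtr[, rep_f$kept, drop = FALSE], ytr,
                lambda = lambda, gamma = gamma),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    pred <- predict(fit, x[test_idx, rep_f$kept, drop = FALSE])
    predicted[test_idx] <- pred$class
    errors[f] <- sum(pred$class != labels[test_idx])
    crr[f] <- 1 - errors[f] / length(test_idx)
    for (i in seq_along(test_idx))
      confusion[as.character(labels[test_idx[i]]),
                as.character(pred$class[i])] <-
        confusion[as.character(labels[test_idx[i]]),
                  as.character(pred$class[i])] + 1L
  }
  structure(list(per_fold_errors = errors, per_fold_crr = crr,
                 mean_crr = mean(crr), confusion = confusion,
                 reports = reports, predicted = predicted,
                 labels = labels, lambda = lambda, gamma = gamma,
                 plan = plan),
            class = "shape_cv")
}

#' @export
print.shape_cv <- function(x, ...) {
  cat("shape_cv:", x$plan$k, "folds, lambda =", x$lambda,
      ", gamma =", x$gamma, "\n")
  cat("  per-fold errors:", paste(x$per_fold_errors, collapse = " "), "\n")
  cat(sprintf("  mean CRR: %.2f%%\n", 100 * x$mean_crr))
  invisible(x)
}

#' @export
summary.shape_cv <- function(object, ...) {
  cat(sprintf("Mean CRR %.2f%% over %d folds (%d / %d misclassified)\n",
              100 * object$mean_crr, object$plan$k,
              sum(object$per_fold_errors), length(object$labels)))
  kept <- vapply(object$reports, function(r) length(r$kept), 0L)
  cat("  descriptors kept per fold:", paste(kept, collapse = " "), "\n")
  cat("  confusion matrix (rows = truth):\n")
  print(object$confusion)
  invisible(object)
}

#' Add uniform noise to a shape-vector matrix
#'
#' Perturbs every entry of column `j` by an independent draw from
#' `uniform(-amplitude * sigma_j, amplitude * sigma_j)`, where `sigma_j` is
#' that descriptor's standard deviation over the full clean matrix
#' (training and test rows alike, computed before any perturbation).
#' Constant columns are left unchanged.
#'
#' @param x samples x descriptors matrix.
#' @param amplitude noise half-range as a multiple of the per-descriptor
#'   standard deviation (default 1).
#' @param seed integer seed.
#' @return perturbed matrix of the same shape.
#' @export
add_shape_noise <- function(x, amplitude = 1, seed = 1L) {
  stopifnot(amplitude >= 0)
  x <- as.matrix(x)
  if (amplitude == 0) return(x)
  sigma <- apply(x, 2, sd)
  noise <- .with_seed(seed, {
    matrix(runif(length(x), -1, 1), nrow(x), ncol(x))
  })
  x + sweep(noise, 2, amplitude * sigma, "*")
}

#' Noise-robustness experiment
#'
#' Runs the identical cross-validation protocol on the clean matrix and on a
#' uniformly perturbed copy, and reports both mean CRRs and their
#' difference. Heavy noise collapses the class signal, so the perturbed run
#' defaults to the top-SNR selection fallback (see
#' [run_cross_validation()]).
#'
#' @param x shape-vector matrix.
#' @param labels class labels.
#' @param plan fold plan.
#' @param thresholds selection thresholds.
#' @param lambda,gamma RDA parameters.
#' @param amplitude noise amplitude in per-descriptor standard deviations.
#' @param seed seed for the noise draw.
#' @param on_empty empty-selection policy for both runs (default `"top"`).
#' @return list of class `noise_experiment` with `clean`, `noisy`
#'   (both `shape_cv`), `amplitude`, and `delta` (clean minus noisy mean
#'   CRR).
#' @export
noise_experiment <- function(x, labels, plan,
                             thresholds = selection_thresholds(),
                             lambda = 0.99, gamma = 0.001,
                             amplitude = 1, seed = 1L,
                             on_empty = "top") {
  clean <- run_cross_validation(x, labels, plan, thresholds,
                                lambda = lambda, gamma = gamma,
                                on_empty = on_empty)
  xn <- add_shape_noise(x, amplitude = amplitude, seed = seed)
  noisy <- run_cross_validation(xn, labels, plan, thresholds,
                                lambda = lambda, gamma = gamma,
                                on_empty = on_empty)
  structure(list(clean = clean, noisy = noisy, amplitude = amplitude,
                 delta = clean$mean_crr - noisy$mean_crr),
            class = "noise_experiment")
}

#' @export
print.noise_experiment <- function(x, ...) {
  cat(sprintf("noise_experiment (amplitude %g sd):\n", x$amplitude))
  cat(sprintf("  clean mean CRR: %.2f%%\n", 100 * x$clean$mean_crr))
  cat(sprintf("  noisy mean CRR: %.2f%%\n", 100 * x$noisy$mean_crr))
  cat(sprintf("  degradation:    %.2f points\n", 100 * x$delta))
  invisible(x)
}

#' Write cross-validation results as JSON (+ confusion CSV)
#'
#' @param cv a `shape_cv` result.
#' @param path output JSON path; the confusion matrix goes to the same stem
#'   with suffix `_confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "shape_cv"))
  out <- list(mean_crr = cv$mean_crr,
              per_fold_crr = cv$per_fold_crr,
              per_fold_errors = cv$per_fold_errors,
              lambda = cv$lambda, gamma = cv$gamma,
              kept_per_fold = lapply(cv$reports, `[[`, "kept"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(as.data.frame.matrix(cv$confusion),
                   sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}
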