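#' Thresholds for the descriptor-reduction filters
#'
#' @param snr_min minimum pairwise signal-to-noise ratio (default 3.00).
#' @param kurtosis_max maximum per-group sample excess kurtosis (default 16.0).
#' @param skewness_max maximum per-group absolute sample skewness
#'   (default 13.4).
#' @param tau_max maximum absolute Kendall tau-b between retained descriptors
#'   (default 0.95).
#' @return list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(snr_min = 3.00, kurtosis_max = 16.0,
                                 skewness_max = 13.4, tau_max = 0.95) {
  stopifnot(is.finite(snr_min), snr_min > 0,
            is.finite(kurtosis_max), is.finite(skewness_max),
            tau_max > 0, tau_max <= 1)
  structure(list(snr_min = snr_min, kurtosis_max = kurtosis_max,
                 skewness_max = skewness_max, tau_max = tau_max),
            class = "selection_thresholds")
}

#' Pairwise signal-to-noise ratio per descriptor
#'
#' For every pair of classes, the SNR of a descriptor is the absolute
#' difference of the class means divided by the larger of the two class
#' standard deviations. With 6 classes there are 15 pairs; the returned
#' value is the maximum over pairs, so a descriptor that separates even a
#' single class pair strongly is retained. If both standard deviations are
#' zero the SNR is 0 for equal means and `Inf` otherwise.
#'
#' @param x numeric matrix, samples in rows, descriptors in columns.
#' @param labels class label per row (coerced to factor).
#' @return numeric vector of per-descriptor maximum SNR, with attribute
#'   `pairs` (the class pairs, columns of a 2-row character matrix).
#' @export
pairwise_snr <- function(x, labels) {
  labels <- factor(labels)
  x <- as.matrix(x)
  cls <- levels(labels)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("insufficient data: every class needs at least 2 samples (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")")
  mu <- do.call(rbind, lapply(cls, function(g)
    colMeans(x[labels == g, , drop = FALSE])))
  sdv <- do.call(rbind, lapply(cls, function(g)
    apply(x[labels == g, , drop = FALSE], 2, sd)))
  rownames(mu) <- rownames(sdv) <- cls
  prs <- utils::combn(cls, 2L)
  best <- rep(0, ncol(x))
  for (j in seq_len(ncol(prs))) {
    g1 <- prs[1, j]; g2 <- prs[2, j]
    num <- abs(mu[g1, ] - mu[g2, ])
    den <- pmax(sdv[g1, ], sdv[g2, ])
    snr <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    best <- pmax(best, snr)
  }
  attr(best, "pairs") <- prs
  best
}

# per-group sample skewness / excess kurtosis maxima for each descriptor;
# zero-variance groups contribute 0 by convention
.group_moments <- function(x, labels) {
  labels <- factor(labels)
  cls <- levels(labels)
  skew_max <- kurt_max <- rep(0, ncol(x))
  for (g in cls) {
    xg <- x[labels == g, , drop = FALSE]
    if (nrow(xg) < 4L) next  # sample moments undefined; contribute 0
    sk <- apply(xg, 2, function(col) {
      if (sd(col) == 0) return(0)
      e1071::skewness(col, type = 2)
    })
    ku <- apply(xg, 2, function(col) {
      if (sd(col) == 0) return(0)
      e1071::kurtosis(col, type = 2)
    })
    skew_max <- pmax(skew_max, abs(sk))
    kurt_max <- pmax(kurt_max, ku)
  }
  list(skewness = skew_max, kurtosis = kurt_max)
}

#' Moment filter: discard heavy-tailed or strongly skewed descriptors
#'
#' Computes sample skewness and sample excess kurtosis per class for each
#' descriptor and discards a descriptor when the maximum over classes
#' exceeds the thresholds (kurtosis over `kurtosis_max`, or absolute
#' skewness over `skewness_max`). Zero-variance groups count as moments 0.
#'
#' @param x samples x descriptors matrix.
#' @param labels class labels.
#' @param thresholds a [selection_thresholds()].
#' @return integer vector of discarded column indices, with attribute
#'   `moments` (list of the per-descriptor maxima used).
#' @export
moment_filter <- function(x, labels, thresholds = selection_thresholds()) {
  x <- as.matrix(x)
  mom <- .group_moments(x, labels)
  drop <- which(mom$kurtosis > thresholds$kurtosis_max |
                  mom$skewness > thresholds$skewness_max)
  attr(drop, "moments") <- mom
  drop
}

# All-pairs Kendall tau-b via sign-matrix crossproduct. For column j let
# S_j(a, b) = sign(x[a, j] - x[b, j]); then sum_{a,b} S_i S_j = 2 (C - D)
# and the tie-corrected denominator follows from the count of nonzero signs.
# Exact tau-b, but BLAS-speed for the many-column case.
.tau_b_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  M <- vapply(seq_len(ncol(x)),
              function(j) as.numeric(sign(outer(x[, j], x[, j], "-"))),
              numeric(n * n))
  S <- crossprod(M)
  denom <- colSums(abs(M)) / 2        # n0 - (tied pairs) per column
  tau <- (S / 2) / sqrt(outer(denom, denom))
  tau[!is.finite(tau)] <- NA_real_
  diag(tau) <- 1
  dimnames(tau) <- list(colnames(x), colnames(x))
  tau
}

#' Correlation filter: drop near-duplicate descriptors
#'
#' Greedy pass over descriptors in order of decreasing SNR (ties broken by
#' lower column index): a candidate is dropped when its absolute Kendall
#' tau-b with any already-kept descriptor exceeds `tau_max`. Being
#' rank-based, tau-b also catches monotone transforms of a kept descriptor.
#'
#' @param x matrix restricted to the descriptors surviving earlier filters.
#' @param snr per-column SNR values (same order as columns of `x`).
#' @param tau_max threshold on `|tau_b|`.
#' @return integer vector of dropped column indices (into `x`), with
#'   attribute `pairs`, a data frame of (dropped, kept, tau) decisions.
#' @export
correlation_filter <- function(x, snr, tau_max = 0.95) {
  x <- as.matrix(x)
  stopifnot(length(snr) == ncol(x))
  ord <- order(-snr, seq_along(snr))
  # all-pairs tau-b in one vectorized pass; NA (constant columns) counts as 0
  tau <- .tau_b_matrix(x)
  tau[is.na(tau)] <- 0
  kept <- integer(0)
  dropped <- integer(0)
  audit <- list()
  for (j in ord) {
    hit <- 0L
    tau_hit <- NA_real_
    for (k in kept) {
      t <- tau[j, k]
      if (abs(t) > tau_max) { hit <- k; tau_hit <- t; break }
    }
    if (hit > 0L) {
      dropped <- c(dropped, j)
      audit[[length(audit) + 1L]] <- data.frame(dropped = j, kept = hit,
                                                tau = tau_hit)
    } else {
      kept <- c(kept, j)
    }
  }
  dropped <- sort(dropped)
  attr(dropped, "pairs") <- if (length(audit)) do.call(rbind, audit)
  else data.frame(dropped = integer(0), kept = integer(0), tau = numeric(0))
  dropped
}

#' Select discriminative descriptors (SNR, moment and correlation filters)
#'
#' Applies, in order: (1) the pairwise-SNR filter, dropping descriptors whose
#' maximum pairwise SNR is below `snr_min`; (2) the moment filter on the
#' survivors; (3) the Kendall tau-b correlation filter, keeping the
#' higher-SNR member of any near-duplicate pair. Must be run on training
#' data only.
#'
#' @param x samples x descriptors matrix (training rows only).
#' @param labels class labels.
#' @param thresholds a [selection_thresholds()].
#' @return object of class `selection_report`: list with `kept` (column
#'   indices into `x`), `snr` (per-descriptor max pairwise SNR),
#'   `moments` (per-survivor maxima; `NA` where not evaluated),
#'   `dropped` (list of index vectors per filter), `correlation_pairs`
#'   (audit data frame), `thresholds`, and `fallback` (`TRUE` when the
#'   caller requested a top-SNR fallback after an empty cascade).
#' @export
select_descriptors <- function(x, labels,
                               thresholds = selection_thresholds()) {
  x <- as.matrix(x)
  p <- ncol(x)
  snr <- pairwise_snr(x, labels)
  snr_keep <- which(snr >= thresholds$snr_min)
  snr_drop <- setdiff(seq_len(p), snr_keep)

  mom_full <- list(skewness = rep(NA_real_, p), kurtosis = rep(NA_real_, p))
  if (length(snr_keep)) {
    md <- moment_filter(x[, snr_keep, drop = FALSE], labels, thresholds)
    mom <- attr(md, "moments")
    mom_full$skewness[snr_keep] <- mom$skewness
    mom_full$kurtosis[snr_keep] <- mom$kurtosis
    mom_drop <- snr_keep[md]
    mom_keep <- setdiff(snr_keep, mom_drop)
  } else {
    mom_drop <- integer(0)
    mom_keep <- integer(0)
  }

  if (length(mom_keep)) {
    cd <- correlation_filter(x[, mom_keep, drop = FALSE], snr[mom_keep],
                             thresholds$tau_max)
    pairs <- attr(cd, "pairs")
    pairs$dropped <- mom_keep[pairs$dropped]
    pairs$kept <- mom_keep[pairs$kept]
    cor_drop <- mom_keep[cd]
    kept <- setdiff(mom_keep, cor_drop)
  } else {
    pairs <- data.frame(dropped = integer(0), kept = integer(0),
                        tau = numeric(0))
    cor_drop <- integer(0)
    kept <- integer(0)
  }

  if (length(kept) == 0L)
    stop(structure(class = c("injuryshape_empty_selection", "error",
                             "condition"),
                   list(message = paste0(
                     "no descriptor survives the filter cascade; ",
                     "consider relaxing the selection thresholds"),
                     call = sys.call(-1))))

  structure(list(kept = kept, snr = snr, moments = mom_full,
                 dropped = list(snr = snr_drop, moments = mom_drop,
                                correlation = cor_drop),
                 correlation_pairs = pairs,
                 thresholds = thresholds,
                 filter_order = c("snr", "moments", "correlation"),
                 fallback = FALSE),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report:", length(x$kept), "descriptors kept of",
      length(x$snr), "\n")
  cat("  dropped: snr", length(x$dropped$snr),
      "| moments", length(x$dropped$moments),
      "| correlation", length(x$dropped$correlation),
      if (isTRUE(x$fallback)) "| top-SNR fallback used" else "", "\n")
  cat("  kept indices:", paste(utils::head(x$kept, 12L), collapse = " "),
      if (length(x$kept) > 12L) "..." else "", "\n")
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report a `selection_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  out <- list(kept = report$kept,
              dropped = report$dropped,
              snr = unclass(report$snr),
              moments = report$moments,
              correlation_pairs = report$correlation_pairs,
              thresholds = unclass(report$thresholds),
              filter_order = report$filter_order,
              fallback = report$fallback)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
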