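six_class_labels <- function(n_per_class = 18) {
  factor(rep(paste0("g", 1:6), each = n_per_class))
}

test_that("stratified folds give 90 training / 18 test with 3 per class", {
  labels <- six_class_labels()
  plan <- make_stratified_folds(labels, k = 6, seed = 1)
  expect_length(plan$test_sets, 6L)
  for (f in plan$test_sets) {
    expect_length(f, 18L)
    expect_true(all(table(labels[f]) == 3L))
    expect_length(setdiff(seq_len(108), f), 90L)
  }
  # union of test folds is a disjoint cover of all 108 samples
  all_idx <- unlist(plan$test_sets)
  expect_length(all_idx, 108L)
  expect_equal(sort(all_idx), 1:108)
  # determinism
  plan2 <- make_stratified_folds(labels, k = 6, seed = 1)
  expect_identical(plan$test_sets, plan2$test_sets)
  expect_false(identical(plan$test_sets,
                         make_stratified_folds(labels, 6, seed = 2)$test_sets))
})

test_that("class sizes not divisible by k are rejected", {
  expect_error(make_stratified_folds(factor(rep(c("a", "b"), c(12, 13))), 6),
               "stratification")
})

test_that("separable classes cross-validate at CRR 1 with exact accounting", {
  toy <- toy_class_matrix(n_per_class = 12, gap = 60)
  plan <- make_stratified_folds(toy$labels, k = 6, seed = 3)
  cv <- run_cross_validation(toy$x, toy$labels, plan)
  expect_equal(cv$per_fold_crr, rep(1, 6))
  expect_equal(cv$mean_crr, 1)
  expect_equal(sum(diag(cv$confusion)), 72L)
  # CRR accounting: mean CRR x total tested = total correct
  expect_equal(cv$mean_crr * length(toy$labels),
               length(toy$labels) - sum(cv$per_fold_errors))
  # mean CRR is the unweighted mean of fold CRRs
  expect_equal(cv$mean_crr, mean(cv$per_fold_crr))
})

test_that("shuffled labels classify at chance level", {
  toy <- toy_class_matrix(n_per_class = 12, gap = 60)
  set.seed(17)
  shuffled <- sample(toy$labels)
  plan <- make_stratified_folds(shuffled, k = 6, seed = 3)
  cv <- run_cross_validation(toy$x, shuffled, plan, on_empty = "top")
  # chance is 1/6; allow a generous binomial band at n = 72
  expect_lt(abs(cv$mean_crr - 1 / 6), 0.2)
})

test_that("cross-validation is reproducible for fixed seeds", {
  toy <- toy_class_matrix(n_per_class = 6)
  plan <- make_stratified_folds(toy$labels, k = 3, seed = 9)
  cv1 <- run_cross_validation(toy$x, toy$labels, plan)
  cv2 <- run_cross_validation(toy$x, toy$labels, plan)
  expect_identical(cv1$per_fold_errors, cv2$per_fold_errors)
  expect_identical(cv1$predicted, cv2$predicted)
})

test_that("feature selection and standardization never read test rows", {
  toy <- toy_class_matrix(n_per_class = 6, gap = 30)
  plan <- make_stratified_folds(toy$labels, k = 3, seed = 2)
  # fallback policy because the fold-1 test rows perturbed below sit in the
  # training sets of the other folds, whose selection may then collapse
  cv <- run_cross_validation(toy$x, toy$labels, plan, on_empty = "top")
  x2 <- toy$x
  x2[plan$test_sets[[1]], ] <- x2[plan$test_sets[[1]], ] + 1e4
  cv2 <- run_cross_validation(x2, toy$labels, plan, on_empty = "top")
  # fold 1 never saw its test rows: identical selection and SNR audit
  expect_identical(cv$reports[[1]]$kept, cv2$reports[[1]]$kept)
  expect_identical(cv$reports[[1]]$snr, cv2$reports[[1]]$snr)
})

test_that("empty selection errors by default and falls back when asked", {
  labels <- six_class_labels(6)
  # identical alternating pattern in every class: every group mean
  # difference is far below the group scatter, so no descriptor can pass
  # SNR 3 in any training split
  x <- matrix(rep(c(-1, 1), length.out = 36), 36, 10) * rep(1:10, each = 36)
  plan <- make_stratified_folds(labels, k = 3, seed = 1)
  expect_error(run_cross_validation(x, labels, plan), "fold 1")
  cv <- run_cross_validation(x, labels, plan, on_empty = "top", n_top = 4)
  expect_true(all(vapply(cv$reports, function(r) isTRUE(r$fallback), TRUE)))
  expect_true(all(vapply(cv$reports, function(r) length(r$kept), 0L) == 4L))
})

test_that("uniform shape noise respects amplitude and the sigma convention", {
  set.seed(21)
  x <- cbind(a = rnorm(200, sd = 2), b = rnorm(200, sd = 0.5),
             const = rep(3, 200))
  expect_identical(add_shape_noise(x, amplitude = 0), x)
  xn <- add_shape_noise(x, amplitude = 1, seed = 5)
  expect_identical(xn[, "const"], x[, "const"])   # sigma = 0 -> unchanged
  dev <- xn - x
  for (col in c("a", "b")) {
    expect_lte(max(abs(dev[, col])), sd(x[, col]))
    expect_gt(max(abs(dev[, col])), 0.5 * sd(x[, col]))  # actually perturbs
  }
  # seeded determinism
  expect_identical(add_shape_noise(x, 1, seed = 5), xn)
  expect_false(identical(add_shape_noise(x, 1, seed = 6), xn))
  # empirical mean shift vanishes with n
  expect_lt(abs(mean(dev[, "a"])), 0.2 * sd(x[, "a"]))
})

test_that("amplitude-0 noise experiments reproduce the clean result", {
  toy <- toy_class_matrix(n_per_class = 6, gap = 40)
  plan <- make_stratified_folds(toy$labels, k = 3, seed = 4)
  ne <- noise_experiment(toy$x, toy$labels, plan, amplitude = 0, seed = 8)
  expect_equal(ne$clean$mean_crr, ne$noisy$mean_crr)
  expect_equal(ne$delta, 0)
})

test_that("noise degrades accuracy monotonically in expectation", {
  # moderate separation so amplitude-1 noise visibly hurts
  crr_at <- function(amp, seed) {
    toy <- toy_class_matrix(n_per_class = 6, gap = 4, seed = 100 + seed)
    plan <- make_stratified_folds(toy$labels, k = 3, seed = seed)
    ne <- noise_experiment(toy$x, toy$labels, plan, amplitude = amp,
                           seed = seed)
    c(clean = ne$clean$mean_crr, noisy = ne$noisy$mean_crr)
  }
  res1 <- vapply(1:5, function(s) crr_at(1, s), numeric(2))
  expect_true(all(res1["noisy", ] <= res1["clean", ]))
  expect_lt(mean(res1["noisy", ]), mean(res1["clean", ]))
  res10 <- vapply(1:3, function(s) crr_at(10, s), numeric(2))
  expect_lt(abs(mean(res10["noisy", ]) - 1 / 6), 0.2)
})

test_that("cross-validation results serialize to JSON", {
  toy <- toy_class_matrix(n_per_class = 6)
  plan <- make_stratified_folds(toy$labels, k = 3, seed = 1)
  cv <- run_cross_validation(toy$x, toy$labels, plan)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_result(cv, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_crr, cv$mean_crr)
  expect_true(file.exists(sub("\\.json$", "_confusion.csv", path)))
})
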