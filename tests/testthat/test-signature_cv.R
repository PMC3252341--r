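test_that("cv_config validates and normalizes kernel names", {
  cfg <- cv_config(kernels = c("rbf", "linear"), costs = c(0.01, 0.1, 1, 10))
  expect_setequal(cfg$kernels, c("radial", "linear"))
  expect_error(cv_config(costs = c(1, -1)), "positive")
  expect_error(cv_config(subset_sizes = 2.5), "integers")
  expect_error(cv_config(n_folds = 1), "n_folds")
})

test_that("filter ranks by training-set p-value with deterministic ties", {
  sep <- separable_matrix(n_per_class = 12, n_features = 30)
  top <- filter_top_s(sep$x, sep$labels, 5)
  expect_equal(top[1], "f001")  # the planted feature wins
  all_feats <- filter_top_s(sep$x, sep$labels, 30)
  expect_setequal(all_feats, rownames(sep$x))
  # constant data: every p is 1, ranking falls back to feature id order
  const <- matrix(1, 6, 10,
                  dimnames = list(paste0("g", 6:1), paste0("s", 1:10)))
  expect_equal(filter_top_s(const, rep(c("case", "control"), 5), 3),
               c("g1", "g2", "g3"))
  expect_error(filter_top_s(const, rep(c("case", "control"), 5), 7),
               "exceeds")
})

test_that("planted feature is selected first in almost all training sets", {
  set.seed(61)
  hits <- vapply(1:40, function(i) {
    n <- 24
    x <- matrix(stats::rnorm(20 * n), 20, n,
                dimnames = list(sprintf("f%02d", 1:20), NULL))
    lab <- rep(c("case", "control"), each = n / 2)
    x[4, lab == "case"] <- x[4, lab == "case"] + 3
    filter_top_s(x, lab, 1) == "f04"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cross-validation separates a separable cohort and not a null one", {
  sep <- separable_matrix(n_per_class = 30, n_features = 50)
  cfg <- cv_config(kernels = "radial", costs = 1, n_repetitions = 5,
                   subset_sizes = c(1, 5), seed = 3)
  res <- cv_evaluate(sep$x, sep$labels, cfg)
  expect_gte(min(res$metrics$accuracy_mean), 0.99)
  # held-out log-odds point the right way
  expect_gt(mean(res$log_odds[sep$labels == "case", 1]), 0)
  expect_lt(mean(res$log_odds[sep$labels == "control", 1]), 0)
  expect_true(all(is.finite(res$log_odds)))

  set.seed(71)
  xn <- matrix(stats::rnorm(50 * 60), 50, 60,
               dimnames = dimnames(sep$x))
  resn <- cv_evaluate(xn, sep$labels, cfg)
  band <- 3 * sqrt(0.25 / 60)
  expect_lt(max(resn$metrics$accuracy_mean), 0.5 + band)
  expect_gt(min(resn$metrics$accuracy_mean), 0.5 - band)
})

test_that("accuracy lies between sensitivity and specificity", {
  sep <- separable_matrix(n_per_class = 15, n_features = 30, shift = 1.5)
  cfg <- cv_config(kernels = "linear", costs = c(0.1, 1),
                   n_repetitions = 3, subset_sizes = c(2, 10), seed = 9)
  res <- cv_evaluate(sep$x, sep$labels, cfg)
  lo <- pmin(res$metrics$sensitivity_mean, res$metrics$specificity_mean)
  hi <- pmax(res$metrics$sensitivity_mean, res$metrics$specificity_mean)
  expect_true(all(res$metrics$accuracy_mean >= lo - 1e-12))
  expect_true(all(res$metrics$accuracy_mean <= hi + 1e-12))
})

test_that("swapping class names swaps sensitivity and specificity", {
  sep <- separable_matrix(n_per_class = 14, n_features = 20, shift = 2)
  cfg <- cv_config(kernels = "radial", costs = 1, n_repetitions = 3,
                   subset_sizes = 5, seed = 13, compute_log_odds = FALSE)
  res1 <- cv_evaluate(sep$x, sep$labels, cfg)
  swapped <- ifelse(sep$labels == "case", "control", "case")
  res2 <- cv_evaluate(sep$x, swapped, cfg)
  expect_equal(res1$metrics$accuracy_mean, res2$metrics$accuracy_mean)
  expect_equal(res1$metrics$sensitivity_mean, res2$metrics$specificity_mean)
  expect_equal(res1$metrics$specificity_mean, res2$metrics$sensitivity_mean)
})

test_that("results are reproducible from data, config and seed", {
  sep <- separable_matrix(n_per_class = 10, n_features = 20, shift = 1)
  cfg <- cv_config(kernels = "radial", costs = 1, n_repetitions = 2,
                   subset_sizes = 5, seed = 17)
  r1 <- cv_evaluate(sep$x, sep$labels, cfg)
  r2 <- cv_evaluate(sep$x, sep$labels, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$log_odds, r2$log_odds)
})

test_that("n_folds larger than the smaller class is reduced with a warning", {
  sep <- separable_matrix(n_per_class = 4, n_features = 10, shift = 3)
  cfg <- cv_config(kernels = "linear", costs = 1, n_folds = 10,
                   n_repetitions = 2, subset_sizes = 2, seed = 5,
                   compute_log_odds = FALSE)
  expect_warning(res <- cv_evaluate(sep$x, sep$labels, cfg), "merged")
  expect_s3_class(res, "signature_cv")
})

test_that("no leakage: label-carrying feature wins, permuted labels do not", {
  # canary: a feature equal to the class label plus tiny noise is always
  # selected on real labels, while permuting the labels drops accuracy to
  # chance (feature selection inside the folds cannot leak the test labels)
  set.seed(29)
  n <- 40
  x <- matrix(stats::rnorm(30 * n), 30, n,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:n)))
  lab <- rep(c("case", "control"), each = n / 2)
  x[9, ] <- as.numeric(lab == "case") + stats::rnorm(n, sd = 0.01)
  expect_equal(filter_top_s(x, lab, 1), "f09")
  cfg <- cv_config(kernels = "radial", costs = 1, n_repetitions = 3,
                   subset_sizes = 3, seed = 7, compute_log_odds = FALSE)
  real <- cv_evaluate(x, lab, cfg)
  expect_gte(real$best$accuracy_mean, 0.95)
  pn <- permutation_null(x, lab, cfg, n_permutations = 10, observed = real)
  expect_lt(max(pn$null_accuracies), 0.5 + 3 * sqrt(0.25 / n) + 0.15)
  expect_gt(pn$percentile, 95)
})

test_that("permutation null is seeded and reproducible", {
  sep <- separable_matrix(n_per_class = 8, n_features = 15, shift = 2)
  cfg <- cv_config(kernels = "linear", costs = 1, n_folds = 4,
                   n_repetitions = 2, subset_sizes = 3, seed = 23,
                   compute_log_odds = FALSE)
  p1 <- permutation_null(sep$x, sep$labels, cfg, n_permutations = 5,
                         observed = 0.9)
  p2 <- permutation_null(sep$x, sep$labels, cfg, n_permutations = 5,
                         observed = 0.9)
  expect_identical(p1$null_accuracies, p2$null_accuracies)
})

test_that("subset sweep table mirrors the parent result and flags the best", {
  sep <- separable_matrix(n_per_class = 10, n_features = 40, shift = 2)
  cfg <- cv_config(kernels = "radial", costs = c(0.1, 1),
                   n_repetitions = 2, subset_sizes = c(2, 10, 20), seed = 3,
                   compute_log_odds = FALSE)
  res <- cv_evaluate(sep$x, sep$labels, cfg)
  tab <- subset_sweep_summary(res)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$is_best), 1)
  b <- tab[tab$is_best, ]
  expect_equal(b$accuracy_mean, res$best$accuracy_mean)
  key <- paste(tab$kernel, tab$cost, tab$s)
  mkey <- paste(res$metrics$kernel, res$metrics$cost, res$metrics$s)
  expect_equal(tab$accuracy_mean, res$metrics$accuracy_mean[match(key, mkey)])
})

test_that("per-training-fold normalization refit is leakage-free and works", {
  raw <- generate_cohort(synthetic_spec(
    n_cases = 12, n_controls = 12, n_features = 60, n_differential = 10,
    n_up = 5, effect_range = c(2, 2.5), noise_multiplicative_sd = 0.1,
    seed = 53))
  m <- summarize_replicates(raw)
  fit <- suppressWarnings(fit_vsn(m))
  e <- transform_vsn(m, fit)
  cfg <- cv_config(kernels = "radial", costs = 1, n_folds = 4,
                   n_repetitions = 2, subset_sizes = 5, seed = 53,
                   compute_log_odds = FALSE, refit_normalization = TRUE)
  expect_error(cv_evaluate(e, raw$labels, cfg), "summarized")
  res <- suppressWarnings(cv_evaluate(e, raw$labels, cfg, summarized = m))
  expect_gte(res$best$accuracy_mean, 0.9)
})

test_that("signal dilution: accuracy grows with subset size up to the signal", {
  raw <- generate_cohort(synthetic_spec(
    n_cases = 20, n_controls = 20, n_features = 100, n_differential = 30,
    n_up = 15, effect_range = c(log(2), log(3)), seed = 37))
  nm <- suppressWarnings(normalize_cohort(raw))
  cfg <- cv_config(kernels = "radial", costs = 1, n_repetitions = 5,
                   subset_sizes = c(5, 30), seed = 37,
                   compute_log_odds = FALSE)
  res <- cv_evaluate(nm$expr, nm$labels, cfg)
  acc <- res$metrics$accuracy_mean
  expect_gte(acc[res$metrics$s == 30], acc[res$metrics$s == 5] - 0.05)
})
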