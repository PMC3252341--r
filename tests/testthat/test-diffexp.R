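test_that("t-test matches the textbook pooled-variance computation", {
  x <- c(1, 2, 3, 4)
  y <- c(3, 4, 5, 6)
  got <- ttest_two_group(x, y)
  # hand computation: pooled variance 5/3 with 6 df
  sp2 <- (3 * stats::var(x) + 3 * stats::var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(got$t, t_hand)
  expect_equal(got$p, 2 * stats::pt(-abs(t_hand), 6))
  # agrees with the reference implementation
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  ref_w <- stats::t.test(x + c(0, 0, 0, 9), y)
  got_w <- ttest_two_group(x + c(0, 0, 0, 9), y, var_equal = FALSE)
  expect_equal(got_w$p, ref_w$p.value)
})

test_that("t-test symmetry and zero-variance policy", {
  x <- c(1, 2, 3)
  expect_equal(ttest_two_group(x, x), list(t = 0, p = 1, df = 4))
  a <- stats::rnorm(8)
  b <- stats::rnorm(6, 1)
  expect_equal(ttest_two_group(a, b)$p, ttest_two_group(b, a)$p)
  expect_equal(ttest_two_group(a, b)$t, -ttest_two_group(b, a)$t)
  const <- ttest_two_group(rep(2, 4), rep(5, 4))
  expect_equal(const$p, 0)
  expect_equal(const$t, -Inf)
  expect_error(ttest_two_group(1, c(1, 2)), "2 values")
})

test_that("vectorized row t-tests equal the scalar operation", {
  set.seed(77)
  x <- matrix(stats::rnorm(50 * 12), 50, 12)
  x[7, ] <- 3  # constant feature hits the zero-variance policy
  is_case <- rep(c(TRUE, FALSE), each = 6)
  rows <- mirscreen:::row_ttests(x, is_case)
  for (k in c(1, 7, 23, 50)) {
    one <- ttest_two_group(x[k, is_case], x[k, !is_case])
    expect_equal(rows$t[k], one$t)
    expect_equal(rows$p[k], one$p)
  }
  rows_w <- mirscreen:::row_ttests(x, is_case, var_equal = FALSE)
  one_w <- ttest_two_group(x[3, is_case], x[3, !is_case], var_equal = FALSE)
  expect_equal(rows_w$p[3], one_w$p)
})

test_that("BH adjustment equals the brute-force step-up on random input", {
  expect_equal(bh_adjust(0.034), 0.034)  # single test: adjusted equals raw
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(19)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # order invariance: adjusted values travel with their p-values
  p <- stats::runif(25)
  o <- sample(25)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "missing")
})

test_that("fold change follows the exp-of-median-difference convention", {
  expect_equal(round(fold_change(7.34, 6.57)$fold_change, 2), 2.16)
  expect_equal(fold_change(7.34, 6.57)$direction, "down")
  expect_equal(round(fold_change(5.10, 5.40)$fold_change, 2), 1.35)
  expect_equal(fold_change(5.10, 5.40)$direction, "up")
  expect_equal(fold_change(3.3, 3.3)$fold_change, 1)
  # symmetric magnitude
  expect_equal(fold_change(2, 5)$fold_change, fold_change(5, 2)$fold_change)
  expect_error(fold_change(1, NaN), "finite")
})

test_that("rank AUC equals brute-force pair counting and folds to >= 0.5", {
  expect_equal(auc_two_group(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(auc_two_group(c(1, 2, 3), c(4, 5, 6)), 1)  # folded
  expect_equal(auc_two_group(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(23)
  for (i in 1:1000) {
    n1 <- sample(1:8, 1)
    n2 <- sample(1:8, 1)
    a <- sample(1:5, n1, replace = TRUE)  # integer draws force ties
    b <- sample(1:5, n2, replace = TRUE)
    expect_equal(auc_two_group(a, b), auc_brute(a, b))
  }
  # invariance under strictly monotone transforms
  a <- stats::rnorm(9)
  b <- stats::rnorm(7, 0.5)
  expect_equal(auc_two_group(exp(a), exp(b)), auc_two_group(a, b))
  expect_error(auc_two_group(numeric(0), 1), "empty")
})

test_that("panel Shapiro-Wilk summary behaves under null and alternative", {
  set.seed(41)
  normal <- matrix(stats::rnorm(100 * 100), 100, 100)
  expect_gt(shapiro_median(normal)$median_p, 0.3)
  expect_lt(shapiro_median(normal)$median_p, 0.7)
  heavy <- matrix(exp(stats::rnorm(100 * 100, sd = 1.5)), 100, 100)
  expect_lt(shapiro_median(heavy)$median_p, 0.01)
  single <- matrix(stats::rnorm(30), 1, 30)
  expect_equal(shapiro_median(single)$median_p,
               stats::shapiro.test(single[1, ])$p.value)
  # constant features are excluded, not propagated
  normal[1, ] <- 2
  sw <- shapiro_median(normal)
  expect_true(is.na(sw$p_values[1]))
  expect_false(is.na(sw$median_p))
})

test_that("differential screen flags planted features and honours policies", {
  raw <- tiny_cohort(seed = 6, n_differential = 10, n_up = 4)
  nm <- suppressWarnings(normalize_cohort(raw))
  de <- run_diffexp(nm$expr, nm$labels, alpha = 0.05)
  expect_equal(nrow(de), 150)
  expect_true(all(de$fold_change >= 1))
  expect_true(all(de$p_adjusted >= de$p_raw))
  expect_true(all(de$auc >= 0.5 & de$auc <= 1))
  expect_equal(de$significant, de$p_adjusted < 0.05)
  # direction consistent with medians, and with t sign when both agree
  expect_equal(de$direction == "up", de$median_case >= de$median_control)
  # constant matrix: nothing significant, all folds exactly 1
  const <- matrix(5, 20, 10)
  lab <- rep(c("case", "control"), each = 5)
  de0 <- run_diffexp(const, lab)
  expect_equal(sum(de0$significant), 0)
  expect_equal(de0$fold_change, rep(1, 20))
  expect_equal(de0$p_raw, rep(1, 20))
  # one-class partitions are rejected
  expect_error(run_diffexp(const, rep("case", 10)), "2 classes")
  expect_error(run_diffexp(const, rep(c("case", "control"), c(9, 1))),
               "2 samples")
})

test_that("screen table sorts by absolute log fold change with stable ties", {
  raw <- tiny_cohort(seed = 8)
  nm <- suppressWarnings(normalize_cohort(raw))
  de <- run_diffexp(nm$expr, nm$labels, sort_by_fold = TRUE)
  lf <- abs(log(de$fold_change))
  expect_true(all(diff(lf) <= 1e-12))
  # works on arbitrary binary partitions, not only case/control labels
  sub <- run_diffexp(nm$expr,
                     rep(c("pT1", "pT2"), length.out = ncol(nm$expr)))
  expect_equal(nrow(sub), nrow(nm$expr))
})
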