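test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_cases = 0), "n_cases")
  expect_error(synthetic_spec(n_features = 10, n_differential = 11),
               "n_differential")
  expect_error(synthetic_spec(n_differential = 5, n_up = 9), "n_up")
  expect_error(synthetic_spec(effect_range = c(-1, 2)), "effect_range")
  expect_error(synthetic_spec(noise_additive_sd = -1), "noise_additive_sd")
  expect_error(synthetic_spec(array_scale_range = c(0, 1)),
               "array_scale_range")
})

test_that("cohort has the study dimensions and complete truth table", {
  raw <- generate_cohort(synthetic_spec(seed = 3))
  expect_equal(dim(raw$intensities), c(105, 1100, 7))
  expect_equal(as.vector(table(raw$labels)), c(57, 48))
  expect_true(all(is.finite(raw$intensities)))
  expect_true(all(raw$intensities >= 0))
  expect_equal(sum(raw$truth$is_differential), 59)
  expect_equal(sum(raw$truth$direction == "up", na.rm = TRUE), 13)
  expect_equal(sum(raw$truth$direction == "down", na.rm = TRUE), 46)
  eff <- abs(raw$truth$effect[raw$truth$is_differential])
  expect_true(all(eff >= log(1.35) & eff <= log(3.12)))
  expect_true(all(raw$truth$effect[!raw$truth$is_differential] == 0))
})

test_that("same spec and seed reproduce the cohort bit for bit", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)
  c <- tiny_cohort(seed = 12)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(tiny_cohort(seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("planted effects are recovered on the normalized scale", {
  # group medians of well-expressed planted features track the signed
  # natural-log effect; features near the additive-noise floor are
  # compressed by the glog transform, so they are excluded by baseline
  raw <- generate_cohort(synthetic_spec(n_cases = 100, n_controls = 100,
                                        seed = 42))
  nm <- suppressWarnings(normalize_cohort(raw))
  de <- run_diffexp(nm$expr, nm$labels)
  tr <- raw$truth
  err <- de$median_case - de$median_control - tr$effect
  well <- tr$is_differential & tr$baseline >= 5
  expect_gt(sum(well), 30)
  expect_lt(stats::quantile(abs(err[well]), 0.9), 0.1)
  expect_lt(max(abs(err[well])), 0.15)
  expect_lt(abs(mean(err[well])), 0.03)  # no systematic bias
})

test_that("a null cohort yields uniform raw p-values downstream", {
  raw <- generate_cohort(synthetic_spec(n_differential = 0, n_up = 0,
                                        seed = 43))
  nm <- suppressWarnings(normalize_cohort(raw))
  de <- run_diffexp(nm$expr, nm$labels)
  expect_gt(stats::ks.test(de$p_raw, "punif")$p.value, 0.01)
})

test_that("qPCR generator plants exact noise-free pair differences", {
  tab <- generate_qpcr_cohort(n_pairs = 4,
                              true_log2_fold = c("miR-x" = -1),
                              ct_noise_sd = 0, seed = 2)
  s <- qpcr_compare(tab, "miR-x")$samples
  wide <- merge(s[s$group == "case", c("pair_id", "dct")],
                s[s$group == "control", c("pair_id", "dct")],
                by = "pair_id")
  # down-regulated by one log2 unit: every case sits one cycle above its pair
  expect_equal(wide$dct.x - wide$dct.y, rep(1, 4))
})

test_that("qPCR cohort has the validation-study layout", {
  tab <- generate_qpcr_cohort(n_pairs = 24, seed = 5)
  expect_s3_class(tab, "qpcr_table")
  expect_equal(length(unique(tab$pair_id)), 24)
  expect_equal(length(unique(tab$sample_id)), 48)
  expect_setequal(unique(tab$mirna_id), c("miR-16", "miR-202", "miR-718"))
  # duplicates per sample per assay
  expect_true(all(table(tab$sample_id, tab$mirna_id) == 2))
  expect_error(generate_qpcr_cohort(n_pairs = 1), "n_pairs")
  expect_error(generate_qpcr_cohort(true_log2_fold = c(1)), "named")
})

test_that("2^-ddCt estimates are unbiased for the planted fold", {
  folds <- vapply(seq_len(200), function(i) {
    tab <- generate_qpcr_cohort(n_pairs = 12,
                                true_log2_fold = c("miR-x" = 1),
                                ct_noise_sd = 0.1, seed = 1000 + i)
    qpcr_compare(tab, "miR-x")$fold$fold
  }, numeric(1))
  mc_se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - 2), max(4 * mc_se, 0.01))
})

test_that("write_cohort emits the plain-text artifact set", {
  dir <- withr::local_tempdir()
  raw <- tiny_cohort(seed = 9)
  paths <- write_cohort(raw, dir)
  expect_true(all(file.exists(paths)))
  lab <- read_labels_tsv(paths[["labels"]])
  expect_equal(as.character(lab), as.character(raw$labels))
  sp <- yaml::read_yaml(paths[["spec"]])
  expect_equal(sp$seed, raw$spec$seed)
  expect_equal(sp$n_features, raw$spec$n_features)
  # intensities file: one row per feature x replicate
  n_lines <- length(readLines(paths[["intensities"]]))
  expect_equal(n_lines, 150 * 7 + 1)
})
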