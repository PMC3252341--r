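#' Configuration for signature cross-validation
#'
#' Settings for [cv_evaluate()]: SVM kernels, the cost grid (decimal powers
#' from 0.01 to 10), the cross-validation layout and the filter subset-size
#' sweep.
#'
#' @param kernels Character subset of `"linear"`, `"polynomial"`,
#'   `"sigmoid"`, `"radial"` (`"rbf"` is accepted as an alias). Default is
#'   the radial basis function kernel, the one behind the headline
#'   signature; pass all four to reproduce a full kernel comparison.
#' @param costs SVM cost grid.
#' @param n_folds Folds per repetition (reduced with a warning when larger
#'   than the smaller class).
#' @param n_repetitions Repetitions of the full k-fold split.
#' @param subset_sizes Filter subset sizes `s` to sweep.
#' @param stratified Stratify folds by class (recommended for imbalanced
#'   cohorts such as 48 cases / 57 controls).
#' @param compute_log_odds Fit the SVM probability model and report
#'   per-sample held-out log-odds (slower; disable for permutation runs).
#' @param refit_normalization Refit the variance-stabilizing normalization
#'   on each training fold (leakage-free variant; requires passing the
#'   summarized matrix to [cv_evaluate()]). Default `FALSE`, the
#'   fit-once-on-everything discovery convention.
#' @param seed Integer seed for fold assignment (and the SVM probability
#'   model's internal resampling).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(kernels = "radial",
                      costs = c(0.01, 0.1, 1, 10),
                      n_folds = 10,
                      n_repetitions = 100,
                      subset_sizes = seq(10, 300, by = 10),
                      stratified = TRUE,
                      compute_log_odds = TRUE,
                      refit_normalization = FALSE,
                      seed = 1L) {
  kernels <- vapply(kernels, function(k) {
    k <- match.arg(k, c("linear", "polynomial", "sigmoid", "radial", "rbf"))
    if (k == "rbf") "radial" else k
  }, character(1), USE.NAMES = FALSE)
  kernels <- unique(kernels)
  if (any(!is.finite(costs)) || any(costs <= 0)) {
    stop("costs must be positive", call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  if (any(subset_sizes < 1) || any(subset_sizes != round(subset_sizes))) {
    stop("subset_sizes must be positive integers", call. = FALSE)
  }
  structure(list(kernels = kernels, costs = costs,
                 n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 subset_sizes = as.integer(sort(unique(subset_sizes))),
                 stratified = isTRUE(stratified),
                 compute_log_odds = isTRUE(compute_log_odds),
                 refit_normalization = isTRUE(refit_normalization),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Rank features by training-set t-test and keep the top s
#'
#' The filter step of the embedded feature selection: features are ranked by
#' ascending raw two-group t-test p-value computed on the training samples
#' only; the first `s` are returned. Ties are broken by feature id, so the
#' ranking is deterministic.
#'
#' @param train_expr Feature x training-sample matrix.
#' @param train_labels Binary labels for the training samples.
#' @param s Number of features to keep.
#' @return Character vector of `s` feature ids, best first.
#' @export
filter_top_s <- function(train_expr, train_labels, s) {
  if (s < 1) stop("s must be >= 1", call. = FALSE)
  if (s > nrow(train_expr)) {
    stop("s (", s, ") exceeds the number of features (", nrow(train_expr),
         ")", call. = FALSE)
  }
  lab <- as_binary_labels(train_labels, ncol(train_expr))
  ids <- rownames(train_expr)
  if (is.null(ids)) ids <- sprintf("f%04d", seq_len(nrow(train_expr)))
  p <- row_ttests(train_expr, lab == "case")$p
  ids[order(p, ids)][seq_len(s)]
}

# Stratified (or plain) fold assignment; returns integer fold per sample.
assign_folds <- function(is_case, k, stratified) {
  n <- length(is_case)
  folds <- integer(n)
  if (stratified) {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(is_case == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

# Every fold's training portion must contain both classes.
folds_ok <- function(folds, is_case, k) {
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(is_case[tr]) || !any(!is_case[tr])) return(FALSE)
  }
  TRUE
}

#' Repeated cross-validated SVM evaluation of miRNA signatures
#'
#' Evaluates multi-feature diagnostic signatures by repeated stratified
#' k-fold cross-validation with filter feature selection embedded in every
#' fold: for each repetition a fresh fold assignment is drawn; in each fold,
#' features are ranked by training-set t-test p-values ([filter_top_s()]),
#' the top `s` are used to train one SVM per (kernel, cost), and the
#' held-out fold is predicted. Confusion counts are pooled across the folds
#' of a repetition; accuracy, sensitivity (case = positive) and specificity
#' are then averaged over repetitions. Per-sample held-out log-odds
#' ln(P(case)/P(control)) come from the SVM's sigmoid-calibrated class
#' probabilities (clamped to \[1e-6, 1-1e-6\]) and are averaged over the
#' repetitions in which the sample was held out.
#'
#' @param expr Feature x sample matrix on the normalized scale.
#' @param labels Binary labels, one per sample (positive class `"case"`).
#' @param config A [cv_config()].
#' @param summarized Optional feature x sample matrix of background-corrected
#'   median intensities; required when `config$refit_normalization` is
#'   `TRUE`, in which case the variance-stabilizing fit is re-estimated on
#'   each training fold and applied to its test fold.
#' @return An object of class `signature_cv`: list with
#'   \describe{
#'     \item{metrics}{data.frame per (kernel, cost, s): mean and sd of
#'       accuracy, sensitivity, specificity over repetitions.}
#'     \item{best}{the metrics row with the highest mean accuracy (ties:
#'       first in grid order).}
#'     \item{rep_accuracy}{repetitions x configurations accuracy matrix.}
#'     \item{log_odds}{samples x configurations matrix of mean held-out
#'       log-odds (`NULL` unless `config$compute_log_odds`).}
#'     \item{config, labels}{inputs, echoed.}
#'   }
#' @export
cv_evaluate <- function(expr, labels, config = cv_config(),
                        summarized = NULL) {
  stopifnot(inherits(config, "cv_config"))
  if (!is.matrix(expr)) stop("expr must be a matrix", call. = FALSE)
  lab <- as_binary_labels(labels, ncol(expr))
  is_case <- lab == "case"
  n <- ncol(expr)
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (max(config$subset_sizes) > nrow(expr)) {
    stop("subset size ", max(config$subset_sizes),
         " exceeds the feature count (", nrow(expr), ")", call. = FALSE)
  }
  if (config$refit_normalization && is.null(summarized)) {
    stop("refit_normalization requires the summarized matrix", call. = FALSE)
  }
  k <- config$n_folds
  min_class <- min(sum(is_case), sum(!is_case))
  if (k > min_class) {
    warning("n_folds (", k, ") exceeds the smaller class (", min_class,
            "); folds merged to ", min_class)
    k <- min_class
  }
  ids <- rownames(expr)
  if (is.null(ids)) {
    ids <- sprintf("f%04d", seq_len(nrow(expr)))
    rownames(expr) <- ids
    if (!is.null(summarized)) rownames(summarized) <- ids
  }
  sample_ids <- colnames(expr)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))

  grid <- expand.grid(kernel = config$kernels, cost = config$costs,
                      s = config$subset_sizes,
                      stringsAsFactors = FALSE)
  n_cfg <- nrow(grid)
  n_rep <- config$n_repetitions
  acc <- sens <- spec <- matrix(NA_real_, n_rep, n_cfg)
  lo_sum <- lo_cnt <- if (config$compute_log_odds) {
    matrix(0, n, n_cfg)
  } else {
    NULL
  }

  with_seed(config$seed, {
    y_all <- factor(ifelse(is_case, "case", "control"),
                    levels = c("control", "case"))
    for (rep_i in seq_len(n_rep)) {
      folds <- assign_folds(is_case, k, config$stratified)
      tries <- 0
      while (!folds_ok(folds, is_case, k)) {
        tries <- tries + 1
        if (tries >= 10) {
          stop("could not draw folds whose training sets contain both ",
               "classes after 10 attempts", call. = FALSE)
        }
        folds <- assign_folds(is_case, k, config$stratified)
      }
      tp <- tn <- fp <- fn <- matrix(0, 1, n_cfg)
      for (f in seq_len(k)) {
        tr <- which(folds != f)
        te <- which(folds == f)
        if (length(te) == 0L) next
        if (config$refit_normalization) {
          vfit <- fit_vsn(summarized[, tr, drop = FALSE])
          etr <- transform_vsn(summarized[, tr, drop = FALSE], vfit)
          # test arrays are mapped with their training-fit neighbours' scale:
          # refit is per-array, so fit test arrays against the frozen rows
          ete <- transform_vsn_new_arrays(summarized[, te, drop = FALSE],
                                          summarized[, tr, drop = FALSE],
                                          vfit)
        } else {
          etr <- expr[, tr, drop = FALSE]
          ete <- expr[, te, drop = FALSE]
        }
        ttp <- row_ttests(etr, is_case[tr])$p
        ord <- ids[order(ttp, ids)]
        y_tr <- y_all[tr]
        for (g in seq_len(n_cfg)) {
          feats <- ord[seq_len(grid$s[g])]
          fit <- e1071::svm(x = t(etr[feats, , drop = FALSE]), y = y_tr,
                            kernel = grid$kernel[g], cost = grid$cost[g],
                            probability = config$compute_log_odds,
                            scale = FALSE)
          xte <- t(ete[feats, , drop = FALSE])
          pred <- stats::predict(fit, xte,
                                 probability = config$compute_log_odds)
          pc <- pred == "case"
          tp[g] <- tp[g] + sum(pc & is_case[te])
          fp[g] <- fp[g] + sum(pc & !is_case[te])
          fn[g] <- fn[g] + sum(!pc & is_case[te])
          tn[g] <- tn[g] + sum(!pc & !is_case[te])
          if (config$compute_log_odds) {
            pr <- attr(pred, "probabilities")
            p_case <- pmin(pmax(pr[, "case"], 1e-6), 1 - 1e-6)
            lo_sum[te, g] <- lo_sum[te, g] + log(p_case / (1 - p_case))
            lo_cnt[te, g] <- lo_cnt[te, g] + 1
          }
        }
      }
      acc[rep_i, ] <- (tp + tn) / n
      sens[rep_i, ] <- tp / (tp + fn)
      spec[rep_i, ] <- tn / (tn + fp)
    }
  })

  cfg_label <- sprintf("%s_c%g_s%d", grid$kernel, grid$cost, grid$s)
  metrics <- data.frame(
    kernel = grid$kernel, cost = grid$cost, s = grid$s,
    accuracy_mean = colMeans(acc), accuracy_sd = apply(acc, 2, stats::sd),
    sensitivity_mean = colMeans(sens),
    sensitivity_sd = apply(sens, 2, stats::sd),
    specificity_mean = colMeans(spec),
    specificity_sd = apply(spec, 2, stats::sd),
    stringsAsFactors = FALSE
  )
  log_odds <- NULL
  if (config$compute_log_odds) {
    log_odds <- lo_sum / pmax(lo_cnt, 1)
    dimnames(log_odds) <- list(sample_ids, cfg_label)
  }
  colnames(acc) <- cfg_label
  structure(list(
    metrics = metrics,
    best = metrics[which.max(metrics$accuracy_mean), , drop = FALSE],
    rep_accuracy = acc,
    log_odds = log_odds,
    config = config,
    labels = lab
  ), class = "signature_cv")
}

# Map held-out arrays onto a training-fold normalization: each new array's
# affine parameters are fit against the training transform's row means.
transform_vsn_new_arrays <- function(m_new, m_train, fit) {
  h_train <- transform_vsn(m_train, fit)
  target <- rowMeans(h_train)
  out <- matrix(NA_real_, nrow(m_new), ncol(m_new),
                dimnames = dimnames(m_new))
  for (j in seq_len(ncol(m_new))) {
    opt <- stats::optim(c(0, 0), function(par) {
      sum((asinh((m_new[, j] - par[1]) / exp(par[2])) - target)^2)
    }, method = "BFGS", control = list(maxit = 200, reltol = 1e-10))
    out[, j] <- asinh((m_new[, j] - opt$par[1]) / exp(opt$par[2]))
  }
  out
}

#' @export
print.signature_cv <- function(x, ...) {
  b <- x$best
  cat("signature_cv:", nrow(x$metrics), "configurations,",
      x$config$n_repetitions, "repetitions of",
      x$config$n_folds, "fold CV\n")
  cat(sprintf(
    "  best: %s kernel, cost %g, s = %d -> accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    b$kernel, b$cost, b$s, 100 * b$accuracy_mean, 100 * b$sensitivity_mean,
    100 * b$specificity_mean))
  invisible(x)
}

#' Permutation null for the cross-validated accuracy
#'
#' Overtraining check: class labels are shuffled (seeded) and the full
#' cross-validated evaluation is re-run on each permutation; the best mean
#' accuracy per permutation forms the null sample against which the real
#' accuracy is placed.
#'
#' @param expr,labels,config As in [cv_evaluate()]. Use a reduced
#'   `n_repetitions` in `config` to bound the runtime.
#' @param n_permutations Number of label permutations.
#' @param observed Optional precomputed `signature_cv` result (or a bare
#'   accuracy) for the real labels; computed if missing.
#' @return List with `null_accuracies` (length `n_permutations`),
#'   `observed_accuracy`, and `percentile` of the observed accuracy within
#'   the null (in percent).
#' @export
permutation_null <- function(expr, labels, config = cv_config(),
                             n_permutations = 20, observed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  lab <- as_binary_labels(labels, ncol(expr))
  if (is.null(observed)) {
    observed <- cv_evaluate(expr, lab, config)
  }
  obs_acc <- if (inherits(observed, "signature_cv")) {
    max(observed$metrics$accuracy_mean)
  } else {
    as.numeric(observed)
  }
  perms <- with_seed(config$seed + 104729L, {
    lapply(seq_len(n_permutations), function(i) sample(lab))
  })
  null_acc <- vapply(seq_len(n_permutations), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    cfg$compute_log_odds <- FALSE
    res <- cv_evaluate(expr, perms[[i]], cfg)
    max(res$metrics$accuracy_mean)
  }, numeric(1))
  list(null_accuracies = null_acc,
       observed_accuracy = obs_acc,
       percentile = 100 * mean(null_acc < obs_acc))
}

#' Tidy subset-size sweep table
#'
#' One row per (kernel, cost, s) with the averaged metrics and a flag on the
#' best configuration; convenient for plotting accuracy, sensitivity and
#' specificity against the signature size.
#'
#' @param result A `signature_cv` result.
#' @return data.frame ordered by kernel, cost, s with an `is_best` column.
#' @export
subset_sweep_summary <- function(result) {
  stopifnot(inherits(result, "signature_cv"))
  tab <- result$metrics
  tab <- tab[order(tab$kernel, tab$cost, tab$s), ]
  best <- result$best
  tab$is_best <- tab$kernel == best$kernel & tab$cost == best$cost &
    tab$s == best$s
  rownames(tab) <- NULL
  tab
}
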