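#' Two-group t-test with an explicit zero-variance policy
#'
#' Unpaired two-tailed t-test of case versus control values. By default the
#' Student (pooled-variance) statistic is used; `var_equal = FALSE` gives the
#' Welch variant. When both groups are constant with equal means the
#' statistic is defined as 0 with p = 1 (no evidence of a difference); with
#' unequal means it is +/-Inf with p = 0.
#'
#' @param x_case,x_control Numeric vectors, at least 2 values each.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return List with elements `t` (case minus control orientation), `p`
#'   (two-sided) and `df`.
#' @export
ttest_two_group <- function(x_case, x_control, var_equal = TRUE) {
  n1 <- length(x_case)
  n2 <- length(x_control)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (anyNA(x_case) || anyNA(x_control)) {
    stop("missing values in input", call. = FALSE)
  }
  m1 <- mean(x_case)
  m2 <- mean(x_control)
  v1 <- stats::var(x_case)
  v2 <- stats::var(x_control)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (m1 == m2) {
      return(list(t = 0, p = 1, df = if (is.finite(df)) df else n1 + n2 - 2))
    }
    return(list(t = sign(m1 - m2) * Inf, p = 0,
                df = if (is.finite(df)) df else n1 + n2 - 2))
  }
  t <- (m1 - m2) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Vectorized row-wise two-group t-tests on a feature x sample matrix.
# Same statistic and zero-variance policy as ttest_two_group().
row_ttests <- function(x, is_case, var_equal = TRUE) {
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  x1 <- x[, is_case, drop = FALSE]
  x2 <- x[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero <- !is.finite(se) | se == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    t[eq] <- 0
    p[eq] <- 1
    ne <- zero & (m1 != m2)
    t[ne] <- sign(m1 - m2)[ne] * Inf
    p[ne] <- 0
  }
  list(t = t, p = p, df = df)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with m p-values sorted
#' ascending, the adjusted value at rank i is
#' \eqn{\min_{j \ge i} \min(1, m p_{(j)} / j)}, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1] with no missing values",
         call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Exp-scale fold change between group medians
#'
#' On the variance-stabilized (natural-log-like) scale, the reported fold
#' change is \eqn{\exp(|median_{case} - median_{control}|)} with a direction
#' label: `"up"` when the case median is at least the control median, else
#' `"down"`. Symmetric in its arguments up to direction.
#'
#' @param median_control,median_case Group medians on the normalized scale
#'   (vectorized).
#' @return List with `fold_change` (>= 1) and `direction`.
#' @examples
#' fold_change(7.34, 6.57)   # 2.16-fold, down
#' fold_change(5.10, 5.40)   # 1.35-fold, up
#' @export
fold_change <- function(median_control, median_case) {
  if (any(!is.finite(median_control)) || any(!is.finite(median_case))) {
    stop("medians must be finite", call. = FALSE)
  }
  d <- median_case - median_control
  list(fold_change = exp(abs(d)),
       direction = ifelse(d >= 0, "up", "down"))
}

#' Rank-based two-group AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic
#' \eqn{U / (n_1 n_2)} (ties counted 1/2), folded to
#' \eqn{\max(u, 1 - u)} so that the reported discrimination accuracy lies in
#' \[0.5, 1\] for both up- and down-regulated features. Invariant under
#' strictly monotone transforms of the values.
#'
#' @param x_case,x_control Numeric vectors, at least 1 value each.
#' @return AUC in \[0.5, 1\].
#' @export
auc_two_group <- function(x_case, x_control) {
  n1 <- length(x_case)
  n2 <- length(x_control)
  if (n1 < 1L || n2 < 1L) stop("empty group", call. = FALSE)
  r <- rank(c(x_case, x_control))
  u <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  max(u, 1 - u)
}

#' Median Shapiro-Wilk p-value of an expression panel
#'
#' Runs a Shapiro-Wilk normality test on every feature across all samples
#' pooled and summarizes the panel by the median p-value. Constant features
#' have no defined test; their p is recorded as `NA` and excluded from the
#' median.
#'
#' @param expr Feature x sample matrix.
#' @return List with `median_p` and the per-feature vector `p_values`.
#' @export
shapiro_median <- function(expr) {
  if (!is.matrix(expr)) stop("expr must be a matrix", call. = FALSE)
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  p <- apply(expr, 1, function(v) {
    if (length(unique(v)) < 2L) return(NA_real_)
    stats::shapiro.test(v)$p.value
  })
  list(median_p = stats::median(p, na.rm = TRUE), p_values = p)
}

#' Differential-expression screen of a normalized expression matrix
#'
#' Per-feature unpaired two-tailed t-tests between the two classes of a
#' binary partition, Benjamini-Hochberg adjustment across the panel,
#' exp-scale fold changes from group medians with direction, and rank-based
#' AUC. Applicable to case versus control or to any binary subgroup
#' partition. Zero-variance features get t = 0, p = 1 (never dropped).
#'
#' @param expr Feature x sample matrix on the normalized scale.
#' @param labels Binary partition: factor/character/logical, one entry per
#'   sample. The positive class is `"case"` when present, otherwise the
#'   second factor level.
#' @param alpha Significance level applied to the adjusted p-values.
#' @param var_equal Student (pooled) or Welch t-test.
#' @param sort_by_fold Order the table by decreasing |ln fold change|
#'   (ties broken by feature id); default keeps input feature order.
#' @return data.frame with one row per feature: `feature_id`,
#'   `median_control`, `median_case`, `fold_change`, `direction`,
#'   `t_statistic`, `p_raw`, `p_adjusted`, `auc`, `significant`.
#' @export
run_diffexp <- function(expr, labels, alpha = 0.05, var_equal = TRUE,
                        sort_by_fold = FALSE) {
  if (!is.matrix(expr)) stop("expr must be a matrix", call. = FALSE)
  lab <- as_binary_labels(labels, ncol(expr))
  is_case <- lab == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("partition must contain at least 2 samples in each class",
         call. = FALSE)
  }
  feature_ids <- rownames(expr)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%04d", seq_len(nrow(expr)))

  tt <- row_ttests(expr, is_case, var_equal = var_equal)
  med_case <- apply(expr[, is_case, drop = FALSE], 1, stats::median)
  med_ctrl <- apply(expr[, !is_case, drop = FALSE], 1, stats::median)
  fc <- fold_change(med_ctrl, med_case)
  auc <- vapply(seq_len(nrow(expr)), function(k) {
    auc_two_group(expr[k, is_case], expr[k, !is_case])
  }, numeric(1))
  p_adj <- bh_adjust(tt$p)

  res <- data.frame(
    feature_id = feature_ids,
    median_control = med_ctrl,
    median_case = med_case,
    fold_change = fc$fold_change,
    direction = fc$direction,
    t_statistic = tt$t,
    p_raw = tt$p,
    p_adjusted = p_adj,
    auc = auc,
    significant = p_adj < alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (sort_by_fold) {
    res <- res[order(-abs(log(res$fold_change)), res$feature_id), ]
    rownames(res) <- NULL
  }
  res
}

# Coerce a user-supplied binary partition to a control/case factor.
as_binary_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop("labels must have one entry per sample", call. = FALSE)
  }
  lab <- as.character(labels)
  if (anyNA(lab)) stop("labels contain missing values", call. = FALSE)
  lv <- unique(lab)
  if (length(lv) != 2L) {
    stop("partition must have exactly 2 classes (got ", length(lv), ")",
         call. = FALSE)
  }
  if ("case" %in% lv) {
    pos <- "case"
  } else {
    pos <- sort(lv)[2]  # deterministic: second class alphabetically
  }
  factor(ifelse(lab == pos, "case", "control"), levels = c("control", "case"))
}

#' Write a differential-expression table as TSV
#'
#' Column order mirrors the discovery-study report: feature, group medians,
#' fold change, direction, raw and adjusted p, AUC, significance. Numbers
#' are written at 6 significant digits; fold changes additionally rounded to
#' 2 decimals in a `fold_change_2dp` column.
#'
#' @param res Result of [run_diffexp()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_diffexp_tsv <- function(res, path) {
  out <- res
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  out$fold_change_2dp <- round(res$fold_change, 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
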