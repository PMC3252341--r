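#' Average replicate Ct values
#'
#' Arithmetic mean of the replicate well Cts of one sample/assay. A
#' replicate spread above `warn_threshold` cycles (a common QC limit for
#' duplicate wells) triggers a warning.
#'
#' @param ct Numeric vector of replicate Ct values (>= 1 value).
#' @param warn_threshold Maximum acceptable replicate range, in cycles.
#' @return The mean Ct, with attribute `flagged` (logical).
#' @export
mean_ct <- function(ct, warn_threshold = 1) {
  if (length(ct) < 1L || anyNA(ct)) {
    stop("need at least one non-missing replicate Ct", call. = FALSE)
  }
  spread <- diff(range(ct))
  flagged <- spread > warn_threshold
  if (flagged) {
    warning(sprintf("replicate Ct spread %.2f cycles exceeds %.2f",
                    spread, warn_threshold))
  }
  structure(mean(ct), flagged = flagged)
}

#' Reference-normalized Ct
#'
#' \eqn{\Delta Ct} = Ct(target) minus the mean Ct of the endogenous
#' reference in the same sample. Shift-invariant: adding a constant to both
#' (e.g. an input-amount effect) leaves it unchanged.
#'
#' @param ct_target,ct_reference_mean Finite Ct values in cycles
#'   (vectorized).
#' @return \eqn{\Delta Ct} in cycles.
#' @export
delta_ct <- function(ct_target, ct_reference_mean) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference_mean))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  ct_target - ct_reference_mean
}

#' Comparative-Ct relative fold change (2^-ddCt)
#'
#' \eqn{\Delta\Delta Ct} = mean \eqn{\Delta Ct}(case) minus mean
#' \eqn{\Delta Ct}(control); the relative expression of cases versus
#' controls is \eqn{2^{-\Delta\Delta Ct}}. With matched pairs the per-pair
#' folds \eqn{2^{-(\Delta Ct_{case} - \Delta Ct_{ctrl})}} are also returned,
#' together with their geometric mean (algebraically identical to the
#' unpaired group fold when pairs are complete) and their arithmetic mean
#' (reported separately; larger under noise by convexity).
#'
#' Because a fold below 1 simply means down-regulation, the result also
#' carries `magnitude` = max(fold, 1/fold) and a direction label, matching
#' the convention of reporting, say, a 5.44-fold *down*-regulation.
#'
#' @param dct_cases,dct_controls Per-sample \eqn{\Delta Ct} values.
#' @param paired Treat the vectors as aligned matched pairs (equal length
#'   required).
#' @return List with `ddct`, `fold` (\eqn{2^{-\Delta\Delta Ct}}),
#'   `magnitude`, `direction` (`"up"`/`"down"`), and when `paired` also
#'   `per_pair_fold`, `fold_geometric`, `fold_arithmetic`.
#' @export
relative_fold_change <- function(dct_cases, dct_controls, paired = FALSE) {
  if (length(dct_cases) < 1L || length(dct_controls) < 1L) {
    stop("need at least one delta-Ct per group", call. = FALSE)
  }
  if (paired && length(dct_cases) != length(dct_controls)) {
    stop("paired fold change needs equal-length, aligned pair vectors",
         call. = FALSE)
  }
  ddct <- mean(dct_cases) - mean(dct_controls)
  fold <- 2^(-ddct)
  out <- list(
    ddct = ddct,
    fold = fold,
    magnitude = max(fold, 1 / fold),
    direction = if (ddct <= 0) "up" else "down"
  )
  if (paired) {
    pp <- 2^(-(dct_cases - dct_controls))
    out$per_pair_fold <- pp
    out$fold_geometric <- exp(mean(log(pp)))
    out$fold_arithmetic <- mean(pp)
  }
  out
}

# Per-sample delta-Ct table for one target, replicate means first.
sample_delta_ct <- function(table, target, warn_threshold = 1) {
  reference <- attr(table, "reference_mirna")
  if (is.null(reference)) reference <- "miR-16"
  tt <- table[table$mirna_id == target, , drop = FALSE]
  rr <- table[table$mirna_id == reference, , drop = FALSE]
  if (nrow(tt) == 0L) {
    stop("target '", target, "' not present in the table", call. = FALSE)
  }
  agg <- function(df) {
    sp <- split(df$ct, df$sample_id)
    data.frame(sample_id = names(sp),
               ct = vapply(sp, mean, numeric(1)),
               flagged = vapply(sp, function(v) diff(range(v)) > warn_threshold,
                                logical(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  at <- agg(tt)
  ar <- agg(rr)
  miss <- setdiff(at$sample_id, ar$sample_id)
  if (length(miss)) {
    stop("no reference (", reference, ") measurements for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  meta <- unique(table[table$mirna_id == target,
                       c("sample_id", "group", "pair_id")])
  out <- merge(at, ar, by = "sample_id", suffixes = c("_target", "_ref"))
  out <- merge(meta, out, by = "sample_id")
  out$dct <- delta_ct(out$ct_target, out$ct_ref)
  out$flagged <- out$flagged_target | out$flagged_ref
  out[order(out$pair_id, out$group),
      c("sample_id", "group", "pair_id", "ct_target", "ct_ref", "dct",
        "flagged")]
}

#' Compare case and control expression of one qPCR target
#'
#' Full comparative-Ct analysis of one target miRNA in a long-format Ct
#' table: replicate wells are averaged per sample, normalized to the
#' endogenous reference (\eqn{\Delta Ct}), groups are compared by an
#' unpaired two-tailed t-test on the \eqn{\Delta Ct} values, the relative
#' fold change \eqn{2^{-\Delta\Delta Ct}} is computed (per matched pair too,
#' when pair ids are present), and the single-marker discrimination is
#' summarized by the AUC of \eqn{-\Delta Ct} (so that higher expression
#' scores higher; higher \eqn{\Delta Ct} means lower expression).
#'
#' @param table A `qpcr_table` (long format: `sample_id`, `group`,
#'   `pair_id`, `mirna_id`, `replicate`, `ct`) with attribute
#'   `reference_mirna`, e.g. from [generate_qpcr_cohort()] or
#'   [read_qpcr_tsv()].
#' @param target Target miRNA id.
#' @param alpha Significance level.
#' @param var_equal Student (pooled) or Welch t-test on \eqn{\Delta Ct}.
#' @param warn_threshold Replicate-spread QC limit in cycles.
#' @return An object of class `qpcr_result`: list with `target`,
#'   `reference`, `samples` (per-sample \eqn{\Delta Ct} data.frame),
#'   `fold` (the [relative_fold_change()] list, paired when pair ids are
#'   complete), `t_statistic`, `p_value`, `significant`, `auc`,
#'   `mean_dct_case`, `mean_dct_control`.
#' @export
qpcr_compare <- function(table, target, alpha = 0.05, var_equal = TRUE,
                         warn_threshold = 1) {
  samples <- sample_delta_ct(table, target, warn_threshold)
  if (length(unique(samples$group)) < 2L) {
    stop("target '", target, "' was not measured in both groups",
         call. = FALSE)
  }
  dct_case <- samples$dct[samples$group == "case"]
  dct_ctrl <- samples$dct[samples$group == "control"]

  paired <- FALSE
  if (!is.null(samples$pair_id) && !anyNA(samples$pair_id)) {
    counts <- table(samples$pair_id, samples$group)
    paired <- all(counts == 1L)
  }
  if (paired) {
    ord <- samples[order(samples$pair_id), ]
    dc <- ord$dct[ord$group == "case"]
    dk <- ord$dct[ord$group == "control"]
    fold <- relative_fold_change(dc, dk, paired = TRUE)
  } else {
    fold <- relative_fold_change(dct_case, dct_ctrl, paired = FALSE)
  }

  tt <- ttest_two_group(dct_case, dct_ctrl, var_equal = var_equal)
  auc <- auc_two_group(-dct_case, -dct_ctrl)
  structure(list(
    target = target,
    reference = attr(table, "reference_mirna"),
    samples = samples,
    fold = fold,
    t_statistic = tt$t,
    p_value = tt$p,
    significant = tt$p < alpha,
    auc = auc,
    mean_dct_case = mean(dct_case),
    mean_dct_control = mean(dct_ctrl)
  ), class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat("qpcr_result:", x$target, "(reference", paste0(x$reference, ")\n"))
  cat(sprintf("  ddCt %.3f -> fold %.2f (%.2f-fold %s-regulation in cases)\n",
              x$fold$ddct, x$fold$fold, x$fold$magnitude,
              x$fold$direction))
  cat(sprintf("  t = %.3f, p = %.4g%s; AUC = %.3f\n", x$t_statistic,
              x$p_value, if (x$significant) " (significant)" else "", x$auc))
  invisible(x)
}

#' Read / write long-format qPCR Ct tables
#'
#' Plain TSV with columns `sample_id`, `group`, `pair_id`, `mirna_id`,
#' `replicate`, `ct`. The reference assay is carried as an attribute.
#'
#' @param path File path.
#' @param reference_mirna Endogenous reference assay id.
#' @return `read_qpcr_tsv`: a `qpcr_table`; `write_qpcr_tsv`: `path`,
#'   invisibly.
#' @export
read_qpcr_tsv <- function(path, reference_mirna = "miR-16") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "mirna_id", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("qPCR table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"pair_id" %in% names(tab)) tab$pair_id <- NA_character_
  if (!is.numeric(tab$ct) || any(!is.finite(tab$ct)) || any(tab$ct <= 0)) {
    stop("Ct values must be positive numbers", call. = FALSE)
  }
  if (!all(unique(tab$group) %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  structure(tab, reference_mirna = reference_mirna,
            class = c("qpcr_table", "data.frame"))
}

#' @rdname read_qpcr_tsv
#' @param table A `qpcr_table`.
#' @export
write_qpcr_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
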