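#' Read a feature-by-sample expression TSV
#'
#' Expects a header row of sample ids and a first column `feature_id`;
#' remaining cells must be decimal-point numbers. Duplicate feature ids,
#' ragged rows and non-numeric cells are rejected with the offending
#' position named.
#'
#' @param path File path.
#' @return Numeric matrix, features x samples, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression TSV has no data rows",
                               call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_col <- length(header)
  if (n_col < 2L) {
    stop("expression TSV needs a feature_id column plus >= 1 sample column",
         call. = FALSE)
  }
  widths <- lengths(cells[-1L])
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L] + 1L
    stop("ragged row ", bad, ": expected ", n_col, " fields, found ",
         widths[bad - 1L], call. = FALSE)
  }
  ids <- vapply(cells[-1L], `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  body <- vapply(cells[-1L], function(r) r[-1L], character(n_col - 1L))
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    row <- (bad - 1L) %% (n_col - 1L) + 1L   # body is (col-1) x rows
    col <- (bad - 1L) %/% (n_col - 1L) + 1L
    stop("non-numeric cell at data row ", col, ", column ", row + 1L,
         " ('", body[bad], "')", call. = FALSE)
  }
  m <- matrix(vals, nrow = n_col - 1L)   # columns = data rows
  out <- t(m)
  dimnames(out) <- list(ids, header[-1L])
  out
}

#' Write a feature-by-sample expression TSV
#'
#' @param m Numeric matrix, features x samples, with dimnames.
#' @param path Output file.
#' @param digits Significant digits written.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(m, path, digits = 6) {
  stopifnot(is.matrix(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("f%04d", seq_len(nrow(m)))
  samples <- colnames(m)
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(ncol(m)))
  tab <- data.frame(feature_id = ids, signif(m, digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("feature_id", samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample label table
#'
#' Two-column TSV: `sample_id`, `group` (`case`/`control`).
#'
#' @param path File path.
#' @return Named factor of groups, names = sample ids.
#' @export
read_labels_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    stop("labels TSV needs columns sample_id and group", call. = FALSE)
  }
  if (!all(tab$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  stats::setNames(factor(tab$group, levels = c("control", "case")),
                  tab$sample_id)
}

#' Write per-array calibration parameters as TSV
#'
#' @param fit A `vsn_fit`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_calibration_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "vsn_fit"))
  ids <- fit$sample_ids
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(fit$offset))
  tab <- data.frame(array = ids, a = signif(fit$offset, 6),
                    b = signif(fit$scale, 6),
                    glog_scale = signif(fit$glog_scale, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
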