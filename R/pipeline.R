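#' Pipeline configuration
#'
#' Assembles the resolved configuration of a full discovery + validation
#' run: synthetic-cohort spec, normalization settings, the
#' differential-expression level, the classifier grid, the qPCR settings,
#' stage toggles, a global seed and the output directory. Round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]); unknown keys are rejected before any compute.
#'
#' @param synthetic Arguments for [synthetic_spec()] (list).
#' @param normalization Arguments for [fit_vsn()] (list:
#'   `trim_fraction`, `max_iter`, `tol`).
#' @param alpha Differential-expression significance level.
#' @param classify Arguments for [cv_config()] (list), or `NULL` to skip
#'   the classification stage.
#' @param n_permutations Label permutations for the overtraining null
#'   (0 skips it).
#' @param qpcr Arguments for [generate_qpcr_cohort()] (list), or `NULL` to
#'   skip the validation stage.
#' @param seed Global seed; stage seeds default to offsets of it.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @param ... Unknown keys; always an error (guards config-file typos).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(),
                            normalization = list(),
                            alpha = 0.05,
                            classify = list(n_repetitions = 10,
                                            subset_sizes = c(10, 60, 240)),
                            n_permutations = 0,
                            qpcr = list(),
                            seed = 1L,
                            out_dir = "mirscreen_run",
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  cfg <- list(synthetic = synthetic, normalization = normalization,
              alpha = alpha, classify = classify,
              n_permutations = n_permutations, qpcr = qpcr,
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("synthetic", "normalization", "alpha", "classify",
             "n_permutations", "qpcr", "seed", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  chk_args <- function(part, fun, label) {
    if (is.null(part)) return(invisible())
    bad <- setdiff(names(part), names(formals(fun)))
    if (length(bad)) {
      stop("unknown ", label, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  chk_args(cfg$synthetic, synthetic_spec, "synthetic")
  chk_args(cfg$normalization, fit_vsn, "normalization")
  chk_args(cfg$classify, cv_config, "classify")
  chk_args(cfg$qpcr, generate_qpcr_cohort, "qpcr")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (cfg$n_permutations < 0) {
    stop("n_permutations must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the discovery and validation pipeline end to end
#'
#' Orchestrates the full analysis on a synthetic cohort: cohort generation,
#' replicate summarization + variance-stabilizing normalization,
#' differential-expression screening, SVM signature cross-validation with
#' optional permutation null, and comparative-Ct qPCR validation. Every
#' artifact is written as plain text into `cfg$out_dir` together with the
#' resolved configuration (YAML), a JSON summary, a log and a MANIFEST; the
#' whole run is reproducible from the config + seed. A stage failure aborts
#' with a stage-named error, retaining partial outputs with the MANIFEST
#' marked incomplete.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`raw`,
#'   `norm`, `diffexp`, `cv`, `perm`, `qpcr`) and `paths` of the artifacts.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  manifest <- file.path(cfg$out_dir, "MANIFEST")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  writeLines("status: INCOMPLETE", manifest)
  logline("mirscreen ", as.character(utils::packageVersion("mirscreen")),
          " | R ", R.version.string, " | global seed ", cfg$seed)
  write_pipeline_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  paths <- character(0)
  stage <- function(name, expr) {
    logline("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate -------------------------------------------------------------
  raw <- stage("simulate", {
    sp <- do.call(synthetic_spec,
                  utils::modifyList(list(seed = cfg$seed), cfg$synthetic))
    generate_cohort(sp)
  })
  paths <- c(paths, write_cohort(raw, file.path(cfg$out_dir, "cohort")))

  # -- normalize ------------------------------------------------------------
  norm <- stage("normalize", {
    do.call(normalize_cohort, c(list(raw), cfg$normalization))
  })
  p <- file.path(cfg$out_dir, "expression_normalized.tsv")
  write_expression_tsv(norm$expr, p)
  paths <- c(paths, p)
  p <- file.path(cfg$out_dir, "calibration.tsv")
  write_calibration_tsv(norm$fit, p)
  paths <- c(paths, p)

  # -- diffexp --------------------------------------------------------------
  de <- stage("diffexp", {
    run_diffexp(norm$expr, norm$labels, alpha = cfg$alpha,
                sort_by_fold = TRUE)
  })
  p <- file.path(cfg$out_dir, "diffexp.tsv")
  write_diffexp_tsv(de, p)
  paths <- c(paths, p)
  sw <- shapiro_median(norm$expr)
  logline("diffexp: ", sum(de$significant), " significant features (",
          sum(de$significant & de$direction == "up"), " up / ",
          sum(de$significant & de$direction == "down"),
          " down) at adjusted p < ", cfg$alpha,
          "; panel median Shapiro-Wilk p = ", signif(sw$median_p, 3))

  # -- classify -------------------------------------------------------------
  cv <- NULL
  perm <- NULL
  if (!is.null(cfg$classify)) {
    cv <- stage("classify", {
      cc <- do.call(cv_config,
                    utils::modifyList(list(seed = cfg$seed + 1L),
                                      cfg$classify))
      cv_evaluate(norm$expr, norm$labels, cc)
    })
    p <- file.path(cfg$out_dir, "cv_sweep.tsv")
    utils::write.table(subset_sweep_summary(cv), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(cv$log_odds)) {
      p <- file.path(cfg$out_dir, "cv_log_odds.tsv")
      lo <- data.frame(sample_id = rownames(cv$log_odds),
                       group = as.character(cv$labels),
                       signif(cv$log_odds, 6),
                       check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(lo, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    jsonlite::write_json(
      c(as.list(cv$best), list(seed = cv$config$seed)),
      file.path(cfg$out_dir, "cv_best.json"),
      auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(cfg$out_dir, "cv_best.json"))
    logline(sprintf(
      "classify: best %s kernel, cost %g, s=%d: accuracy %.1f%% / sensitivity %.1f%% / specificity %.1f%%",
      cv$best$kernel, cv$best$cost, cv$best$s, 100 * cv$best$accuracy_mean,
      100 * cv$best$sensitivity_mean, 100 * cv$best$specificity_mean))

    if (cfg$n_permutations > 0) {
      perm <- stage("permutation", {
        cc <- cv$config
        cc$n_repetitions <- max(1L, cc$n_repetitions %/% 5L)
        permutation_null(norm$expr, norm$labels, cc,
                         n_permutations = cfg$n_permutations,
                         observed = cv)
      })
      p <- file.path(cfg$out_dir, "permutation_null.tsv")
      utils::write.table(
        data.frame(permutation = seq_along(perm$null_accuracies),
                   accuracy = signif(perm$null_accuracies, 6)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
      logline(sprintf(
        "permutation: observed accuracy %.3f at percentile %.1f of %d-permutation null",
        perm$observed_accuracy, perm$percentile,
        length(perm$null_accuracies)))
    }
  }

  # -- qpcr -----------------------------------------------------------------
  qp <- NULL
  if (!is.null(cfg$qpcr)) {
    qp <- stage("qpcr", {
      tab <- do.call(generate_qpcr_cohort,
                     utils::modifyList(list(seed = cfg$seed + 2L), cfg$qpcr))
      targets <- setdiff(unique(tab$mirna_id), attr(tab, "reference_mirna"))
      list(table = tab,
           results = lapply(stats::setNames(targets, targets),
                            function(tg) qpcr_compare(tab, tg,
                                                      alpha = cfg$alpha)))
    })
    p <- file.path(cfg$out_dir, "qpcr_ct.tsv")
    write_qpcr_tsv(qp$table, p)
    paths <- c(paths, p)
    res_tab <- do.call(rbind, lapply(qp$results, function(r) {
      data.frame(mirna_id = r$target,
                 relative_fold_change = signif(r$fold$magnitude, 6),
                 direction = r$fold$direction,
                 fold_2_neg_ddct = signif(r$fold$fold, 6),
                 p_value = signif(r$p_value, 6),
                 auc = signif(r$auc, 6),
                 stringsAsFactors = FALSE)
    }))
    p <- file.path(cfg$out_dir, "qpcr_results.tsv")
    utils::write.table(res_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(cfg$out_dir, "qpcr_delta_ct.tsv")
    dct <- do.call(rbind, lapply(qp$results, function(r) {
      cbind(mirna_id = r$target, r$samples)
    }))
    utils::write.table(dct, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    for (r in qp$results) {
      logline(sprintf("qpcr %s: %.2f-fold %s-regulation, p = %.4g, AUC %.3f",
                      r$target, r$fold$magnitude, r$fold$direction,
                      r$p_value, r$auc))
    }
  }

  # -- summary --------------------------------------------------------------
  summary <- list(
    seed = cfg$seed,
    n_samples = length(norm$labels),
    n_features = nrow(norm$expr),
    n_significant = sum(de$significant),
    n_up = sum(de$significant & de$direction == "up"),
    n_down = sum(de$significant & de$direction == "down"),
    shapiro_median_p = sw$median_p
  )
  if (!is.null(cv)) {
    summary$best_accuracy <- cv$best$accuracy_mean
    summary$best_sensitivity <- cv$best$sensitivity_mean
    summary$best_specificity <- cv$best$specificity_mean
    summary$best_subset_size <- cv$best$s
  }
  if (!is.null(perm)) summary$permutation_percentile <- perm$percentile
  if (!is.null(qp)) {
    summary$qpcr <- lapply(qp$results, function(r) {
      list(fold = r$fold$magnitude, direction = r$fold$direction,
           p = r$p_value)
    })
  }
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(cfg$out_dir, "summary.json"))

  writeLines(c("status: COMPLETE", basename(paths)), manifest)
  logline("pipeline complete: ", length(paths), " artifacts in ",
          cfg$out_dir)
  invisible(list(raw = raw, norm = norm, diffexp = de, cv = cv, perm = perm,
                 qpcr = qp, paths = paths))
}
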