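#' Specification of a synthetic whole-blood miRNA microarray cohort
#'
#' Defines the dimensions, planted effects and noise model of a simulated
#' case-control miRNA profiling study. Defaults emulate a discovery cohort of
#' 48 early-stage breast-cancer cases and 57 healthy controls measured on a
#' 1100-feature miRNA panel with 7 within-array replicate spots per feature,
#' of which 59 features carry a true group effect (13 up, 46 down in cases)
#' with natural-log effect sizes drawn uniformly from \[ln 1.35, ln 3.12\],
#' the fold-change range of the most deregulated panel members.
#'
#' The intensity model is the multiplicative-additive error model that
#' variance-stabilizing normalization assumes: for sample i, feature k,
#' replicate r,
#' \deqn{x_{ikr} = a_i + b_i \exp(\mu_k + \delta_k 1[case_i] + \eta_{ik})
#'   + \nu_{ikr} + bg}
#' with per-array affine calibration (offset \eqn{a_i}, scale \eqn{b_i}),
#' latent log-abundances \eqn{\mu_k}, signed planted effects \eqn{\delta_k},
#' log-scale biological/array noise \eqn{\eta_{ik}}, additive measurement
#' noise \eqn{\nu_{ikr}} in intensity units, and a constant per-array
#' background \eqn{bg}.
#'
#' @param n_cases,n_controls Number of case and control samples.
#' @param n_features Panel size (features = miRNAs + star sequences).
#' @param n_replicates Within-array replicate spots per feature.
#' @param n_differential Number of features with a planted group effect.
#' @param n_up How many of the planted effects are up-regulated in cases.
#' @param effect_range Range (natural-log scale) the absolute effect sizes
#'   are drawn from, uniformly.
#' @param baseline_mean,baseline_sd Normal distribution of the latent
#'   per-feature log-abundances \eqn{\mu_k}.
#' @param noise_multiplicative_sd Standard deviation of the log-scale noise
#'   \eqn{\eta_{ik}} (shared by the replicates of a spot).
#' @param noise_additive_sd Standard deviation of the per-replicate additive
#'   noise \eqn{\nu_{ikr}}, in intensity units.
#' @param array_offset_range,array_scale_range Uniform ranges for the
#'   per-array calibration offset \eqn{a_i} and scale \eqn{b_i}.
#' @param background Constant per-array background intensity.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   bit for bit.
#'
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
synthetic_spec <- function(n_cases = 48,
                           n_controls = 57,
                           n_features = 1100,
                           n_replicates = 7,
                           n_differential = 59,
                           n_up = 13,
                           effect_range = c(log(1.35), log(3.12)),
                           baseline_mean = 7,
                           baseline_sd = 2,
                           noise_multiplicative_sd = 0.25,
                           noise_additive_sd = 20,
                           array_offset_range = c(50, 200),
                           array_scale_range = c(0.8, 1.25),
                           background = 30,
                           seed = 1L) {
  spec <- list(
    n_cases = n_cases, n_controls = n_controls, n_features = n_features,
    n_replicates = n_replicates, n_differential = n_differential,
    n_up = n_up, effect_range = effect_range,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_multiplicative_sd = noise_multiplicative_sd,
    noise_additive_sd = noise_additive_sd,
    array_offset_range = array_offset_range,
    array_scale_range = array_scale_range,
    background = background, seed = as.integer(seed)
  )
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  chk_count <- function(field, min = 1) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < min ||
        v != round(v)) {
      stop("invalid synthetic_spec field '", field, "': must be an integer >= ",
           min, call. = FALSE)
    }
  }
  for (f in c("n_cases", "n_controls", "n_features", "n_replicates")) {
    chk_count(f)
  }
  chk_count("n_differential", min = 0)
  chk_count("n_up", min = 0)
  if (spec$n_differential > spec$n_features) {
    stop("invalid synthetic_spec field 'n_differential': exceeds n_features",
         call. = FALSE)
  }
  if (spec$n_up > spec$n_differential) {
    stop("invalid synthetic_spec field 'n_up': exceeds n_differential",
         call. = FALSE)
  }
  if (length(spec$effect_range) != 2L || any(!is.finite(spec$effect_range)) ||
      any(spec$effect_range <= 0) || diff(spec$effect_range) < 0) {
    stop("invalid synthetic_spec field 'effect_range': need 0 < lo <= hi",
         call. = FALSE)
  }
  for (f in c("noise_multiplicative_sd", "noise_additive_sd")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("invalid synthetic_spec field '", f, "': must be >= 0",
           call. = FALSE)
    }
  }
  if (!is.finite(spec$baseline_mean) || !is.finite(spec$baseline_sd) ||
      spec$baseline_sd < 0) {
    stop("invalid synthetic_spec field 'baseline_mean/baseline_sd'",
         call. = FALSE)
  }
  if (length(spec$array_offset_range) != 2L ||
      any(!is.finite(spec$array_offset_range)) ||
      diff(spec$array_offset_range) < 0) {
    stop("invalid synthetic_spec field 'array_offset_range'", call. = FALSE)
  }
  if (length(spec$array_scale_range) != 2L ||
      any(!is.finite(spec$array_scale_range)) ||
      any(spec$array_scale_range <= 0) ||
      diff(spec$array_scale_range) < 0) {
    stop("invalid synthetic_spec field 'array_scale_range': scales must be > 0",
         call. = FALSE)
  }
  if (!is.finite(spec$background) || spec$background < 0) {
    stop("invalid synthetic_spec field 'background': must be >= 0",
         call. = FALSE)
  }
  if (is.na(spec$seed)) {
    stop("invalid synthetic_spec field 'seed'", call. = FALSE)
  }
  invisible(spec)
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a replicate-level synthetic microarray cohort
#'
#' Draws a raw intensity tensor (sample x feature x replicate) from the
#' multiplicative-additive error model described in [synthetic_spec()],
#' together with group labels and a ground-truth table of planted effects.
#' Intensities are truncated at zero (fluorescence is non-negative).
#'
#' @param spec A [synthetic_spec()] object.
#' @return An object of class `raw_cohort`: a list with elements
#'   \describe{
#'     \item{intensities}{numeric array, samples x features x replicates,
#'       with dimnames.}
#'     \item{background}{the constant per-array background that was added.}
#'     \item{labels}{factor of `"control"`/`"case"` per sample.}
#'     \item{truth}{data.frame with `feature_id`, `is_differential`,
#'       `direction` (`"up"`/`"down"`/`NA`), signed natural-log `effect` and
#'       the latent log-abundance `baseline` of every feature.}
#'     \item{array_params}{data.frame of the true per-array `offset`/`scale`
#'       used (simulation metadata, useful for calibration recovery checks).}
#'     \item{spec}{the generating spec, seed included.}
#'   }
#' @examples
#' raw <- generate_cohort(synthetic_spec(n_cases = 4, n_controls = 4,
#'                                       n_features = 50, n_differential = 5,
#'                                       n_up = 2, seed = 7))
#' dim(raw$intensities)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    spec <- do.call(synthetic_spec, spec)
  }
  validate_synthetic_spec(spec)
  n_s <- spec$n_cases + spec$n_controls
  n_f <- spec$n_features
  n_r <- spec$n_replicates

  sample_ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
                  sprintf("ctrl_%03d", seq_len(spec$n_controls)))
  feature_ids <- sprintf("miR-sim-%04d", seq_len(n_f))
  labels <- factor(rep(c("case", "control"),
                       c(spec$n_cases, spec$n_controls)),
                   levels = c("control", "case"))

  out <- with_seed(spec$seed, {
    mu <- stats::rnorm(n_f, spec$baseline_mean, spec$baseline_sd)
    delta <- numeric(n_f)
    diff_idx <- integer(0)
    direction <- rep(NA_character_, n_f)
    if (spec$n_differential > 0) {
      diff_idx <- sort(sample.int(n_f, spec$n_differential))
      up_idx <- if (spec$n_up > 0) {
        sample(diff_idx, spec$n_up)
      } else {
        integer(0)
      }
      sizes <- stats::runif(spec$n_differential,
                            spec$effect_range[1], spec$effect_range[2])
      sgn <- ifelse(diff_idx %in% up_idx, 1, -1)
      delta[diff_idx] <- sgn * sizes
      direction[diff_idx] <- ifelse(sgn > 0, "up", "down")
    }
    a <- stats::runif(n_s, spec$array_offset_range[1],
                      spec$array_offset_range[2])
    b <- stats::runif(n_s, spec$array_scale_range[1],
                      spec$array_scale_range[2])
    eta <- matrix(stats::rnorm(n_s * n_f, 0, spec$noise_multiplicative_sd),
                  n_s, n_f)
    is_case <- as.numeric(labels == "case")
    # latent spot intensity on each array, shared by its replicates
    latent <- exp(matrix(mu, n_s, n_f, byrow = TRUE) +
                    outer(is_case, delta) + eta)
    signal <- a + b * latent  # recycles a, b down columns (samples)
    x <- array(0, dim = c(n_s, n_f, n_r),
               dimnames = list(sample_ids, feature_ids, NULL))
    for (r in seq_len(n_r)) {
      x[, , r] <- signal + spec$background +
        stats::rnorm(n_s * n_f, 0, spec$noise_additive_sd)
    }
    x[x < 0] <- 0
    list(x = x, a = a, b = b, delta = delta, mu = mu,
         is_differential = seq_len(n_f) %in% diff_idx,
         direction = direction)
  })

  truth <- data.frame(
    feature_id = feature_ids,
    is_differential = out$is_differential,
    direction = out$direction,
    effect = out$delta,
    baseline = out$mu,
    stringsAsFactors = FALSE
  )
  structure(list(
    intensities = out$x,
    background = spec$background,
    labels = labels,
    truth = truth,
    array_params = data.frame(sample_id = sample_ids,
                              offset = out$a, scale = out$b,
                              stringsAsFactors = FALSE),
    spec = spec
  ), class = "raw_cohort")
}

#' @export
print.raw_cohort <- function(x, ...) {
  d <- dim(x$intensities)
  cat("raw_cohort:", d[1], "samples x", d[2], "features x", d[3],
      "replicates\n")
  cat("  groups:", sum(x$labels == "case"), "case /",
      sum(x$labels == "control"), "control\n")
  if (!is.null(x$truth)) {
    cat("  planted differential features:", sum(x$truth$is_differential), "\n")
  }
  invisible(x)
}

#' Generate a synthetic matched-pair RT-qPCR Ct table
#'
#' Simulates a validation experiment of `n_pairs` age-matched case-control
#' pairs measured in replicate wells for one or more target miRNAs plus an
#' endogenous reference (default miR-16). The Ct model is
#' \deqn{Ct_{target} = Ct_{ref,sample} + dCt_0 + \beta_{pair}
#'   - log_2fold \cdot 1[case] + \epsilon}
#' so that the per-sample \eqn{\Delta Ct} (target minus reference mean) of a
#' case sits `true_log2_fold` cycles *below* its matched control when the
#' target is up-regulated (lower Ct = more template). Sample-level reference
#' shifts cancel in \eqn{\Delta Ct}; pair-level baselines \eqn{\beta} cancel
#' in the group mean \eqn{\Delta\Delta Ct} when pairs are complete.
#'
#' Defaults mirror the validation study: 24 pairs, duplicate wells, and two
#' targets planted at the validated relative fold changes (miR-202 up
#' 19.38-fold, miR-718 down 5.44-fold).
#'
#' @param n_pairs Number of matched case-control pairs (>= 2).
#' @param true_log2_fold Named numeric vector: planted log2 expression fold
#'   change in cases per target miRNA (positive = up-regulated).
#' @param ct_noise_sd Per-well technical noise, in cycles.
#' @param n_replicates Wells per sample per assay.
#' @param pair_baseline_sd Between-pair biological spread of the target
#'   \eqn{\Delta Ct} baseline, in cycles.
#' @param sample_ct_sd Between-sample spread of reference-level Ct (RNA
#'   input variation; cancels in \eqn{\Delta Ct}).
#' @param reference_mirna Endogenous control assay name.
#' @param ref_ct_mean,dct_base Mean reference Ct and baseline target
#'   \eqn{\Delta Ct}, in cycles.
#' @param seed Integer seed.
#' @return A `qpcr_table`: a long-format data.frame with columns
#'   `sample_id`, `group`, `pair_id`, `mirna_id`, `replicate`, `ct`, with
#'   attributes `reference_mirna` and `truth` (the planted log2 folds).
#' @export
generate_qpcr_cohort <- function(n_pairs = 24,
                                 true_log2_fold = c("miR-202" = log2(19.38),
                                                    "miR-718" = -log2(5.44)),
                                 ct_noise_sd = 0.1,
                                 n_replicates = 2,
                                 pair_baseline_sd = 1,
                                 sample_ct_sd = 1,
                                 reference_mirna = "miR-16",
                                 ref_ct_mean = 20,
                                 dct_base = 5,
                                 seed = 1L) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 2 ||
      n_pairs != round(n_pairs)) {
    stop("n_pairs must be an integer >= 2", call. = FALSE)
  }
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  if (is.null(names(true_log2_fold)) || any(!nzchar(names(true_log2_fold)))) {
    stop("true_log2_fold must be a named vector (one entry per target miRNA)",
         call. = FALSE)
  }
  if (reference_mirna %in% names(true_log2_fold)) {
    stop("the reference miRNA cannot also be a target", call. = FALSE)
  }
  targets <- names(true_log2_fold)
  n_s <- 2L * n_pairs
  pair_id <- rep(sprintf("pair_%02d", seq_len(n_pairs)), each = 2L)
  group <- rep(c("case", "control"), n_pairs)
  sample_id <- paste0(pair_id, "_", group)

  tab <- with_seed(seed, {
    ref_level <- ref_ct_mean + stats::rnorm(n_s, 0, sample_ct_sd)
    rows <- vector("list", length(targets) + 1L)
    mk <- function(mirna, ct_level) {
      data.frame(
        sample_id = rep(sample_id, each = n_replicates),
        group = rep(group, each = n_replicates),
        pair_id = rep(pair_id, each = n_replicates),
        mirna_id = mirna,
        replicate = rep(seq_len(n_replicates), n_s),
        ct = rep(ct_level, each = n_replicates) +
          stats::rnorm(n_s * n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE
      )
    }
    rows[[1L]] <- mk(reference_mirna, ref_level)
    for (j in seq_along(targets)) {
      beta <- rep(stats::rnorm(n_pairs, 0, pair_baseline_sd), each = 2L)
      level <- ref_level + dct_base + beta -
        true_log2_fold[j] * (group == "case")
      rows[[j + 1L]] <- mk(targets[j], level)
    }
    do.call(rbind, rows)
  })
  if (any(tab$ct <= 0)) tab$ct[tab$ct <= 0] <- 0.01  # Ct must stay positive
  rownames(tab) <- NULL
  structure(tab,
            reference_mirna = reference_mirna,
            truth = true_log2_fold,
            class = c("qpcr_table", "data.frame"))
}

#' Write a raw cohort to plain-text files
#'
#' Writes the replicate-level intensities as a wide TSV (one row per feature
#' x replicate, one column per sample), the labels, the truth table and the
#' generating spec (YAML) into a directory.
#'
#' @param raw A `raw_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(raw, dir) {
  stopifnot(inherits(raw, "raw_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(raw$intensities)
  sample_ids <- dimnames(raw$intensities)[[1]]
  feature_ids <- dimnames(raw$intensities)[[2]]
  # long-by-spot layout: feature x replicate rows, sample columns
  flat <- matrix(aperm(raw$intensities, c(2, 3, 1)), nrow = d[2] * d[3],
                 dimnames = list(NULL, sample_ids))
  tab <- data.frame(
    feature_id = rep(feature_ids, times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[2]),
    flat, check.names = FALSE, stringsAsFactors = FALSE
  )
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.tsv"),
    spec = file.path(dir, "spec.yaml")
  )
  utils::write.table(tab, paths["intensities"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = sample_ids, group = as.character(raw$labels)),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(raw$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(raw$spec), paths["spec"])
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `intensities.tsv`, `labels.tsv` and
#'   optionally `truth.tsv` and `spec.yaml`.
#' @return A `raw_cohort` (truth and spec present only if their files are).
#' @export
read_cohort <- function(dir) {
  ipath <- file.path(dir, "intensities.tsv")
  tab <- utils::read.delim(ipath, check.names = FALSE)
  if (!all(c("feature_id", "replicate") %in% names(tab))) {
    stop("intensities.tsv needs feature_id and replicate columns",
         call. = FALSE)
  }
  labels <- read_labels_tsv(file.path(dir, "labels.tsv"))
  sample_ids <- names(labels)
  miss <- setdiff(sample_ids, names(tab))
  if (length(miss)) {
    stop("intensities.tsv lacks column(s) for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  feature_ids <- unique(tab$feature_id)
  reps <- sort(unique(tab$replicate))
  x <- array(NA_real_,
             dim = c(length(sample_ids), length(feature_ids), length(reps)),
             dimnames = list(sample_ids, feature_ids, NULL))
  for (r in seq_along(reps)) {
    block <- tab[tab$replicate == reps[r], , drop = FALSE]
    block <- block[match(feature_ids, block$feature_id), , drop = FALSE]
    x[, , r] <- t(as.matrix(block[, sample_ids, drop = FALSE]))
  }
  spec_path <- file.path(dir, "spec.yaml")
  spec <- if (file.exists(spec_path)) {
    sp <- yaml::read_yaml(spec_path)
    structure(sp, class = "synthetic_spec")
  } else {
    NULL
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  background <- if (!is.null(spec)) spec$background else 0
  structure(list(intensities = x, background = background, labels = labels,
                 truth = truth, array_params = NULL, spec = spec),
            class = "raw_cohort")
}
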