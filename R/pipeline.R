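#' Pearson correlation of per-subject PRL counts with 95% CI
#'
#' @param predicted_counts,reference_counts Per-subject integer counts
#'   (same subjects, same order; >= 3 subjects, nonzero variance).
#' @return One-row tibble: `r`, `ci_low`, `ci_high` (Fisher-z interval).
#' @export
count_correlation <- function(predicted_counts, reference_counts) {
  stopifnot(length(predicted_counts) == length(reference_counts))
  if (length(predicted_counts) < 3) stop("need at least 3 subjects")
  if (stats::var(predicted_counts) == 0 || stats::var(reference_counts) == 0) {
    stop("counts have zero variance")
  }
  ct <- stats::cor.test(predicted_counts, reference_counts,
                        method = "pearson", conf.level = 0.95)
  tibble::tibble(r = unname(ct$estimate),
                 ci_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
                 ci_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_)
}

#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `phantom` (a [phantom_spec()], plus `n_subjects`) or
#' `subject_dirs` (directories each holding phase.nii.gz, prob_map.nii.gz,
#' gold_mask.nii.gz, csf_mask.nii.gz, gm_mask.nii.gz, prl_annotation.nii.gz)
#' must be supplied.
#'
#' @param phantom Optional [phantom_spec()].
#' @param n_subjects Subjects to simulate in phantom mode.
#' @param subject_dirs Optional character vector of real-data directories.
#' @param thresholds Candidate binarization thresholds.
#' @param smooth_sigma_vox Centre-detection smoothing sigma.
#' @param include_size Include lesion size as a predictor.
#' @param n_train_subjects,min_lesions Split parameters.
#' @param smote_k SMOTE neighbour count.
#' @param n_folds,n_trees,tune Classifier parameters.
#' @param n_iter Resampling iterations for empirical CIs (0 to skip).
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A validated `aprl_config` list.
#' @export
aprl_config <- function(phantom = NULL, n_subjects = 20, subject_dirs = NULL,
                        thresholds = seq(0.05, 0.95, by = 0.05),
                        smooth_sigma_vox = 1, include_size = FALSE,
                        n_train_subjects = 16, min_lesions = 100,
                        smote_k = 5, n_folds = 10, n_trees = 500,
                        tune = TRUE, n_iter = 0, seed = 1,
                        out_dir = tempfile("aprl_run_")) {
  if (is.null(phantom) == is.null(subject_dirs)) {
    stop("exactly one of `phantom` or `subject_dirs` must be provided")
  }
  structure(list(phantom = phantom, n_subjects = n_subjects,
                 subject_dirs = subject_dirs, thresholds = thresholds,
                 smooth_sigma_vox = smooth_sigma_vox,
                 include_size = include_size,
                 n_train_subjects = n_train_subjects,
                 min_lesions = min_lesions, smote_k = smote_k,
                 n_folds = n_folds, n_trees = n_trees, tune = tune,
                 n_iter = n_iter, seed = seed, out_dir = out_dir),
            class = "aprl_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; the `phantom` block, when present, is passed
#' to [phantom_spec()].
#'
#' @param path YAML file.
#' @return An `aprl_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(aprl_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$phantom)) {
    raw$phantom <- do.call(phantom_spec, raw$phantom)
  }
  do.call(aprl_config, raw)
}

load_subject_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(phase = read_volume(p("phase.nii.gz"), "phase"),
       prob_map = read_volume(p("prob_map.nii.gz"), "probability"),
       gold_mask = read_volume(p("gold_mask.nii.gz"), "mask"),
       csf_mask = read_volume(p("csf_mask.nii.gz"), "mask"),
       gm_mask = read_volume(p("gm_mask.nii.gz"), "mask"),
       prl_annotation = read_volume(p("prl_annotation.nii.gz"), "mask"))
}

#' Run the full PRL pipeline
#'
#' Orchestrates phantom generation (or real-data loading), lesion
#' labelling, feature extraction, subject-level splitting, classifier
#' training, evaluation (full test set and non-confluent subset), the
#' per-subject PRL count correlation against the reference, and optional
#' resampling confidence intervals. All artifacts are persisted under
#' `cfg$out_dir` together with a manifest recording parameters, seeds and
#' content checksums of every written file.
#'
#' @param cfg An [aprl_config()].
#' @return An `aprl_run` list: `features`, `records`, `split`, `model`,
#'   `performance`, `performance_nonconfluent`, `counts`,
#'   `count_correlation`, `importance`, `ci` (or `NULL`), `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "aprl_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ## ---- inputs ----
  cases <- stage("input", {
    if (!is.null(cfg$phantom)) {
      logf("generating %d phantom subjects (seed %d)", cfg$n_subjects, cfg$seed)
      generate_cohort(cfg$n_subjects, cfg$phantom, seed = cfg$seed)
    } else {
      logf("loading %d subject directories", length(cfg$subject_dirs))
      cs <- lapply(cfg$subject_dirs, load_subject_dir)
      names(cs) <- basename(cfg$subject_dirs)
      cs
    }
  })

  ## ---- labelling + features ----
  subjects <- names(cases)
  per_subject <- stage("labelling", {
    lapply(subjects, function(sid) {
      cs <- cases[[sid]]
      lab <- label_lesions(cs$prob_map, cs$gold_mask, cs$csf_mask, cs$gm_mask,
                           cs$prl_annotation, thresholds = cfg$thresholds,
                           smooth_sigma_vox = cfg$smooth_sigma_vox,
                           subject_id = sid)
      feats <- extract_feature_table(cs$phase, lab$labels, lab$records,
                                     include_size = cfg$include_size)
      logf("%s: threshold %.2f, %d lesions (%d PRL)", sid, lab$threshold,
           lab$n_lesions, lab$n_prl)
      list(labelling = lab, features = feats,
           truth_rims = if (!is.null(cs$truth)) sum(cs$truth$is_rim) else NA_integer_)
    })
  })
  names(per_subject) <- subjects
  features <- dplyr::bind_rows(lapply(per_subject, `[[`, "features"))
  records <- dplyr::bind_rows(lapply(per_subject, function(x) x$labelling$records))

  counts <- tibble::tibble(
    subject_id = subjects,
    n_lesions = vapply(per_subject, function(x) x$labelling$n_lesions, integer(1)),
    n_prl = vapply(per_subject, function(x) x$labelling$n_prl, integer(1)),
    n_rim_truth = vapply(per_subject, function(x) as.integer(x$truth_rims), integer(1)))
  corr <- if (!anyNA(counts$n_rim_truth)) {
    stage("count_correlation",
          count_correlation(counts$n_prl, counts$n_rim_truth))
  } else NULL

  ## ---- classification ----
  smote_cfg <- smote_config(k_neighbors = cfg$smote_k, seed = cfg$seed)
  split <- stage("split", split_by_subject(features, cfg$n_train_subjects,
                                           cfg$min_lesions,
                                           seed = derive_seed(cfg$seed, 0)))
  tr <- features[features$subject_id %in% split$train_subjects, , drop = FALSE]
  te <- features[features$subject_id %in% split$test_subjects, , drop = FALSE]
  logf("split: %d train / %d test lesions (%d / %d PRL)", nrow(tr), nrow(te),
       sum(tr$is_prl_truth), sum(te$is_prl_truth))
  model <- stage("train", train_prl_classifier(
    tr, smote_cfg, n_folds = cfg$n_folds, n_trees = cfg$n_trees,
    tune = cfg$tune, seed = derive_seed(cfg$seed, 1)))
  perf <- stage("evaluate", evaluate_classifier(model, te, "youden"))
  perf_nc <- stage("evaluate_nonconfluent", tryCatch(
    evaluate_classifier(model, te, "youden", exclude_confluent = TRUE),
    error = function(e) NULL))
  imp <- stage("importance", permutation_importance(
    model, te, seed = derive_seed(cfg$seed, 2)))
  ci <- if (cfg$n_iter >= 2) {
    stage("resample_ci", resample_ci(
      features, n_iter = cfg$n_iter, n_train_subjects = cfg$n_train_subjects,
      min_lesions = cfg$min_lesions, smote_cfg = smote_cfg,
      n_folds = cfg$n_folds, n_trees = cfg$n_trees, tune = cfg$tune,
      seed = derive_seed(cfg$seed, 3)))
  } else NULL

  ## ---- persist ----
  out <- cfg$out_dir
  stage("write", {
    utils::write.csv(records, file.path(out, "records.csv"), row.names = FALSE)
    utils::write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
    utils::write.csv(counts, file.path(out, "subject_counts.csv"), row.names = FALSE)
    utils::write.csv(imp, file.path(out, "importance.csv"), row.names = FALSE)
    for (sid in subjects) {
      # uncompressed NIfTI: gzip embeds a timestamp, which would break
      # bitwise reproducibility of the manifest checksums
      write_volume(per_subject[[sid]]$labelling$labels,
                   file.path(out, sprintf("labels_%s.nii", sid)), "labels")
    }
    report <- c(list(auc = perf$auc, threshold = perf$threshold,
                     confusion = as.list(perf$confusion)),
                as.list(perf$measures[, c("accuracy", "ppv", "npv", "fpr",
                                          "fnr", "sensitivity", "specificity")]))
    if (!is.null(perf_nc)) {
      report$nonconfluent <- list(auc = perf_nc$auc,
                                  threshold = perf_nc$threshold,
                                  confusion = as.list(perf_nc$confusion))
    }
    if (!is.null(corr)) report$count_correlation <- as.list(corr)
    if (!is.null(ci)) report$ci <- ci$ci
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  params <- cfg
  params$phantom <- unclass(params$phantom)
  files <- sort(setdiff(list.files(out), c("manifest.json", "run.log")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("aprl")),
    parameters = unclass(params),
    seed = cfg$seed,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("run complete: %s", out)

  structure(list(features = features, records = records, split = split,
                 model = model, performance = perf,
                 performance_nonconfluent = perf_nc, counts = counts,
                 count_correlation = corr, importance = imp, ci = ci,
                 manifest = manifest, out_dir = out), class = "aprl_run")
}
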