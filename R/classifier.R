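#' Feature columns of a lesion feature table
#'
#' Numeric predictor columns: the 44 first-order features plus `size_vox`
#' when present; identifier and label columns are excluded.
#'
#' @param tab Feature table.
#' @return Character vector of predictor column names.
#' @export
feature_columns <- function(tab) {
  drop <- c("subject_id", "lesion_id", "is_confluent", "is_prl_truth",
            "synthetic")
  nm <- setdiff(names(tab), drop)
  nm[vapply(tab[nm], is.numeric, logical(1))]
}

#' Split a lesion cohort into training and test sets by subject
#'
#' Subjects (never individual lesions) are assigned uniformly at random to
#' the two sides; the draw is repeated until both sides carry at least
#' `min_lesions` lesions, so no subject's lesions are ever divided across
#' the split.
#'
#' @param features Feature table with a `subject_id` column.
#' @param n_train_subjects Number of training subjects.
#' @param min_lesions Minimum lesions required on each side.
#' @param seed RNG seed.
#' @param max_retries Redraw budget before giving up.
#' @return List with `train_subjects`, `test_subjects`.
#' @export
split_by_subject <- function(features, n_train_subjects, min_lesions = 100,
                             seed = 1, max_retries = 100) {
  subjects <- unique(features$subject_id)
  if (length(subjects) <= n_train_subjects) {
    stop("cohort must have more subjects than n_train_subjects")
  }
  counts <- table(features$subject_id)
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    tr <- sample(subjects, n_train_subjects)
    te <- setdiff(subjects, tr)
    if (sum(counts[tr]) >= min_lesions && sum(counts[te]) >= min_lesions) {
      return(list(train_subjects = sort(tr), test_subjects = sort(te)))
    }
  }
  stop("could not find a subject split meeting the minimum lesion counts")
}

#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest minority neighbours interpolation
#'   candidates are drawn from.
#' @param oversample_factor Target multiplier for the minority class;
#'   `"auto"` uses the reciprocal of minority prevalence, so classes end up
#'   balanced without undersampling the majority.
#' @param seed RNG seed.
#' @return A `smote_config` list.
#' @export
smote_config <- function(k_neighbors = 5L, oversample_factor = "auto",
                         seed = 1L) {
  stopifnot(k_neighbors >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 oversample_factor = oversample_factor,
                 seed = as.integer(seed)), class = "smote_config")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Rebalances a lesion feature table by interpolating synthetic minority
#' rows: repeatedly pick a minority row, pick one of its `k_neighbors`
#' nearest minority neighbours (Euclidean distance in feature space), and
#' emit `row + u * (neighbour - row)` with `u ~ Uniform(0, 1)`. Majority
#' rows pass through unchanged; nothing is undersampled. The number of
#' synthetic rows is `round((factor - 1) * n_minority)`.
#'
#' @param features Feature table with logical label column.
#' @param cfg A [smote_config()].
#' @param label_col Name of the logical minority-indicator column.
#' @return The input rows (order preserved) followed by synthetic minority
#'   rows; a logical `synthetic` column marks the generated rows.
#' @export
smote_oversample <- function(features, cfg = smote_config(),
                             label_col = "is_prl_truth") {
  y <- features[[label_col]]
  stopifnot(is.logical(y))
  cols <- feature_columns(features)
  n_min <- sum(y)
  factor <- cfg$oversample_factor
  if (identical(factor, "auto")) factor <- length(y) / n_min
  n_syn <- round((factor - 1) * n_min)
  out <- features
  out$synthetic <- FALSE
  if (n_syn <= 0) return(out)
  if (n_min <= cfg$k_neighbors) {
    stop("minority class must have more rows than k_neighbors")
  }
  minority <- as.matrix(features[y, cols, drop = FALSE])
  dmat <- as.matrix(stats::dist(minority))
  diag(dmat) <- Inf
  k <- cfg$k_neighbors
  nn_idx <- apply(dmat, 1, function(r) order(r)[seq_len(k)])  # k x n_min
  set.seed(cfg$seed)
  base <- sample.int(n_min, n_syn, replace = TRUE)
  pick <- sample.int(k, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  nb <- nn_idx[cbind(pick, base)]
  syn_mat <- minority[base, , drop = FALSE] +
    u * (minority[nb, , drop = FALSE] - minority[base, , drop = FALSE])
  syn <- features[which(y)[base], , drop = FALSE]
  syn[, cols] <- as.data.frame(syn_mat)
  syn$synthetic <- TRUE
  dplyr::bind_rows(out, syn)
}

#' Area under the ROC curve by the rank statistic
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half (Mann-Whitney formulation).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical labels (TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-J optimal classification threshold
#'
#' Evaluates `J(t) = sensitivity(t) + specificity(t) - 1` at every distinct
#' score under the rule "positive iff score >= t" and returns the smallest
#' threshold achieving the maximum.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical labels.
#' @return The selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("Youden threshold requires both classes")
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    sens <- sum(labels & scores >= t) / n_pos
    spec <- sum(!labels & scores < t) / n_neg
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Derive the eight performance measures from a confusion table
#'
#' @param tn,fp,fn,tp Confusion counts (reference in rows, prediction in
#'   columns; positives are PRLs).
#' @return One-row tibble: accuracy, ppv, npv, fpr, fnr, sensitivity,
#'   specificity, and the counts.
#' @export
performance_measures <- function(tn, fp, fn, tp) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    tn = tn, fp = fp, fn = fn, tp = tp,
    accuracy = (tp + tn) / (tn + fp + fn + tp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    fpr = 1 - spec,
    fnr = 1 - sens,
    sensitivity = sens,
    specificity = spec)
}

#' Train the PRL random-forest classifier
#'
#' SMOTE-balanced probability random forest with 10-fold cross-validation.
#' When `tune = TRUE` the number of candidate features per split (`mtry`)
#' is tuned over `{sqrt(p), p/3, p/2}` by out-of-fold AUC; SMOTE is applied
#' inside each training fold so synthetic rows never leak into the fold
#' used for validation (set `smote_inside_folds = FALSE` to rebalance once
#' up front instead). The final forest is fit on the SMOTE-augmented full
#' training set.
#'
#' @param train Feature table with `is_prl_truth` labels.
#' @param smote_cfg A [smote_config()].
#' @param n_folds Cross-validation folds.
#' @param n_trees Trees in the forest.
#' @param tune Tune `mtry` by cross-validation; otherwise use `sqrt(p)`.
#' @param seed RNG seed (controls folds, SMOTE draws and forest growth).
#' @param smote_inside_folds Apply SMOTE within each CV training fold.
#' @return A `prl_classifier` object.
#' @export
train_prl_classifier <- function(train, smote_cfg = smote_config(),
                                 n_folds = 10, n_trees = 500, tune = TRUE,
                                 seed = 1, smote_inside_folds = TRUE) {
  y <- train$is_prl_truth
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  cols <- feature_columns(train)
  p <- length(cols)
  mtry_grid <- if (tune) {
    sort(unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2)))))
  } else {
    pmax(1L, floor(sqrt(p)))
  }

  fit_rf <- function(dat, mtry, fit_seed) {
    df <- as.data.frame(dat[, cols, drop = FALSE])
    df$.y <- factor(dat$is_prl_truth, levels = c(FALSE, TRUE))
    ranger::ranger(.y ~ ., data = df, num.trees = n_trees, mtry = mtry,
                   probability = TRUE, seed = fit_seed, num.threads = 1)
  }
  score_rf <- function(fit, dat) {
    pr <- stats::predict(fit, as.data.frame(dat[, cols, drop = FALSE]),
                         num.threads = 1)$predictions
    pr[, "TRUE"]
  }

  cv <- NULL
  if (length(mtry_grid) > 1 || n_folds > 1) {
    set.seed(derive_seed(seed, 0))
    # class-stratified folds so every training fold sees both classes
    fold <- integer(length(y))
    fold[y] <- sample(rep(seq_len(n_folds), length.out = sum(y)))
    fold[!y] <- sample(rep(seq_len(n_folds), length.out = sum(!y)))
    oof <- matrix(NA_real_, length(y), length(mtry_grid))
    for (f in seq_len(n_folds)) {
      tr <- train[fold != f, , drop = FALSE]
      if (smote_inside_folds) {
        cfg_f <- smote_cfg
        cfg_f$seed <- derive_seed(seed, f)
        tr <- smote_oversample(tr, cfg_f)
      }
      for (g in seq_along(mtry_grid)) {
        fit <- fit_rf(tr, mtry_grid[g], derive_seed(seed, 1000 + f * 10 + g))
        oof[fold == f, g] <- score_rf(fit, train[fold == f, , drop = FALSE])
      }
    }
    cv <- tibble::tibble(
      mtry = mtry_grid,
      cv_auc = vapply(seq_along(mtry_grid),
                      function(g) auc_rank(oof[, g], y), numeric(1)))
    best_mtry <- cv$mtry[which.max(cv$cv_auc)]
  } else {
    best_mtry <- mtry_grid[1]
  }

  cfg_full <- smote_cfg
  cfg_full$seed <- derive_seed(seed, 999983)
  aug <- smote_oversample(train, cfg_full)
  model <- fit_rf(aug, best_mtry, derive_seed(seed, 999989))
  structure(list(model = model, mtry = best_mtry, cv = cv,
                 feature_names = cols, n_trees = n_trees,
                 smote_cfg = smote_cfg, seed = seed,
                 n_train = nrow(train)), class = "prl_classifier")
}

#' Predict PRL probabilities
#'
#' @param object A `prl_classifier`.
#' @param newdata Feature table.
#' @param ... Unused.
#' @return Numeric vector of PRL probabilities.
#' @export
predict.prl_classifier <- function(object, newdata, ...) {
  df <- as.data.frame(newdata[, object$feature_names, drop = FALSE])
  stats::predict(object$model, df, num.threads = 1)$predictions[, "TRUE"]
}

#' Evaluate a PRL classifier on a test set
#'
#' Scores the test lesions, fixes the operating point (Youden-J on the test
#' scores, or a supplied probability threshold), and derives the full
#' performance report: AUC by the rank statistic, the confusion table under
#' the "positive iff score >= threshold" rule, and the eight derived
#' measures. With `exclude_confluent = TRUE` the report is recomputed on
#' the non-confluent subset only, including a subset-specific Youden
#' threshold.
#'
#' @param model A `prl_classifier`.
#' @param test Feature table with `is_prl_truth` (and `is_confluent` when
#'   subsetting).
#' @param threshold `"youden"` or a probability in `(0, 1)`.
#' @param exclude_confluent Drop lesions flagged as confluent first.
#' @return A `prl_performance` object.
#' @export
evaluate_classifier <- function(model, test, threshold = "youden",
                                exclude_confluent = FALSE) {
  if (exclude_confluent) {
    test <- test[!test$is_confluent, , drop = FALSE]
  }
  if (nrow(test) == 0) stop("empty test set")
  y <- test$is_prl_truth
  scores <- stats::predict(model, test)
  auc <- auc_rank(scores, y)
  thr <- if (identical(threshold, "youden")) {
    youden_threshold(scores, y)
  } else {
    as.numeric(threshold)
  }
  pred <- scores >= thr
  meas <- performance_measures(tn = sum(!y & !pred), fp = sum(!y & pred),
                               fn = sum(y & !pred), tp = sum(y & pred))
  structure(list(auc = auc, threshold = thr,
                 confusion = c(tn = meas$tn, fp = meas$fp,
                               fn = meas$fn, tp = meas$tp),
                 measures = meas, scores = scores, labels = y,
                 n = nrow(test),
                 exclude_confluent = exclude_confluent),
            class = "prl_performance")
}

#' Empirical confidence intervals by repeated resplitting
#'
#' Repeats the whole protocol - subject-level resplit, SMOTE, forest
#' training, Youden operating point, evaluation - `n_iter` times with
#' derived seeds and reports per-measure empirical 2.5/97.5 percentile
#' intervals. Any single iteration is reproducible in isolation through
#' the counter-based seed scheme.
#'
#' @param features Full-cohort feature table.
#' @param n_iter Number of resplits (the published protocol uses 1000;
#'   smaller values are supported for desk-scale work).
#' @param n_train_subjects,min_lesions Split parameters.
#' @param smote_cfg A [smote_config()].
#' @param n_folds,n_trees,tune Classifier parameters per iteration.
#' @param seed Master seed.
#' @return List with `replicates` (one row per iteration) and `ci`
#'   (per-measure `ci_low`/`ci_high`).
#' @export
resample_ci <- function(features, n_iter = 1000, n_train_subjects = 16,
                        min_lesions = 100, smote_cfg = smote_config(),
                        n_folds = 10, n_trees = 500, tune = TRUE, seed = 1) {
  stopifnot(n_iter >= 2)
  reps <- purrr::map_dfr(seq_len(n_iter), function(it) {
    s <- derive_seed(seed, it)
    sp <- split_by_subject(features, n_train_subjects, min_lesions, seed = s)
    tr <- features[features$subject_id %in% sp$train_subjects, , drop = FALSE]
    te <- features[features$subject_id %in% sp$test_subjects, , drop = FALSE]
    fit <- train_prl_classifier(tr, smote_cfg, n_folds = n_folds,
                                n_trees = n_trees, tune = tune, seed = s)
    perf <- evaluate_classifier(fit, te, threshold = "youden")
    dplyr::bind_cols(tibble::tibble(iteration = it, auc = perf$auc,
                                    threshold = perf$threshold),
                     perf$measures[, c("accuracy", "ppv", "npv", "fpr",
                                       "fnr", "sensitivity", "specificity")])
  })
  meas_cols <- c("auc", "threshold", "accuracy", "ppv", "npv", "fpr", "fnr",
                 "sensitivity", "specificity")
  ci <- purrr::map_dfr(meas_cols, function(mc) {
    # inverse-ECDF percentiles: empirical order statistics, so two
    # replicates give exactly their min/max
    qs <- stats::quantile(reps[[mc]], c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE, type = 1)
    tibble::tibble(measure = mc, ci_low = qs[1], ci_high = qs[2])
  })
  list(replicates = reps, ci = ci)
}

#' Permutation variable importance
#'
#' For each feature: permute the column, re-predict, and report the percent
#' increase in mean-squared error over the unpermuted predictions,
#' `100 * (MSE_perm - MSE_base) / MSE_base`, averaged over `n_rep`
#' permutations. The scaled variant divides the mean increase by its
#' across-repetition standard deviation for comparability across features.
#'
#' @param model A `prl_classifier`.
#' @param data Feature table with labels (>= 2 rows).
#' @param n_rep Permutation repetitions (>= 3 for the scaled variant).
#' @param seed RNG seed.
#' @return Tibble: `feature`, `raw_importance` (percent MSE increase),
#'   `scaled_importance`, sorted by decreasing raw importance.
#' @export
permutation_importance <- function(model, data, n_rep = 5, seed = 1) {
  stopifnot(nrow(data) >= 2)
  y <- as.numeric(data$is_prl_truth)
  base_mse <- mean((stats::predict(model, data) - y)^2)
  cols <- model$feature_names
  set.seed(seed)
  incr <- matrix(NA_real_, length(cols), n_rep,
                 dimnames = list(cols, NULL))
  for (r in seq_len(n_rep)) {
    for (j in seq_along(cols)) {
      perm <- data
      perm[[cols[j]]] <- sample(perm[[cols[j]]])
      mse <- mean((stats::predict(model, perm) - y)^2)
      incr[j, r] <- 100 * (mse - base_mse) / base_mse
    }
  }
  sds <- apply(incr, 1, stats::sd)
  out <- tibble::tibble(
    feature = cols,
    raw_importance = rowMeans(incr),
    scaled_importance = ifelse(sds > 0, rowMeans(incr) / sds, 0))
  dplyr::arrange(out, dplyr::desc(.data$raw_importance))
}
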