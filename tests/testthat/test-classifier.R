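# small separable feature cohort for classifier unit tests
toy_cohort <- function(n_subjects = 10, per_subject = 30, prev = 0.2,
                       sep = 3, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    n <- per_subject
    y <- runif(n) < prev
    tibble::tibble(
      subject_id = sprintf("T%02d", s),
      lesion_id = seq_len(n),
      f1 = rnorm(n) + sep * y,
      f2 = rnorm(n) - sep * y,
      f3 = rnorm(n),
      is_confluent = FALSE,
      is_prl_truth = y)
  })
}

test_that("subject splits are disjoint, deterministic and size-checked", {
  cohort <- toy_cohort(20)
  sp <- split_by_subject(cohort, 16, min_lesions = 100, seed = 5)
  expect_length(sp$train_subjects, 16)
  expect_length(sp$test_subjects, 4)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  sp2 <- split_by_subject(cohort, 16, min_lesions = 100, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_by_subject(cohort, 16, min_lesions = 1e5, seed = 5),
               "minimum lesion")
  expect_error(split_by_subject(cohort, 25, seed = 1), "more subjects")
})

test_that("SMOTE: identity at factor 1, auto factor, segment geometry", {
  cohort <- toy_cohort(6, seed = 2)
  out1 <- smote_oversample(cohort, smote_config(oversample_factor = 1))
  expect_equal(dplyr::select(out1, -synthetic), cohort)
  expect_false(any(out1$synthetic))

  prev <- mean(cohort$is_prl_truth)
  auto <- smote_oversample(cohort, smote_config(oversample_factor = "auto",
                                                seed = 3))
  n_min <- sum(cohort$is_prl_truth)
  expect_equal(sum(auto$synthetic), round((1 / prev - 1) * n_min))
  # majority rows bit-identical and in place
  expect_identical(auto[!auto$synthetic & !auto$is_prl_truth, names(cohort)],
                   cohort[!cohort$is_prl_truth, ])

  # every synthetic row sits on a segment between a minority row and one of
  # its k nearest minority neighbours (exhaustive k-NN)
  k <- 5
  minority <- as.matrix(cohort[cohort$is_prl_truth, c("f1", "f2", "f3")])
  nn_sets <- oracle_knn_sets(minority, k)
  syn <- as.matrix(auto[auto$synthetic, c("f1", "f2", "f3")])
  on_segment <- function(srow) {
    for (i in seq_len(nrow(minority))) {
      for (j in nn_sets[[i]]) {
        dv <- minority[j, ] - minority[i, ]
        rel <- srow - minority[i, ]
        if (all(abs(dv) < 1e-12)) next
        u <- sum(rel * dv) / sum(dv * dv)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((rel - u * dv)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))
  expect_error(
    smote_oversample(cohort[c(which(cohort$is_prl_truth)[1:3],
                              which(!cohort$is_prl_truth)), ],
                     smote_config(oversample_factor = 2)),
    "k_neighbors")
})

test_that("AUC matches the pairwise oracle and is monotone-invariant", {
  set.seed(7)
  for (rep in 1:5) {
    scores <- sample(round(runif(50), 2))   # includes ties
    labels <- runif(50) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels))
    expect_equal(auc_rank(exp(3 * scores), labels), auc_rank(scores, labels))
  }
  expect_error(auc_rank(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Youden threshold: perfect separation case and exhaustive scan", {
  scores <- c(0.9, 0.8, 0.1, 0.2)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(youden_threshold(scores, labels), 0.8)
  set.seed(8)
  for (rep in 1:10) {
    sc <- round(runif(40), 2)
    lb <- runif(40) < 0.5
    if (!any(lb) || all(lb)) next
    expect_equal(youden_threshold(sc, lb), oracle_youden(sc, lb))
  }
  # independent labels: J at the optimum stays near zero for large n
  set.seed(9)
  sc <- runif(4000); lb <- runif(4000) < 0.5
  t0 <- youden_threshold(sc, lb)
  j <- mean(sc[lb] >= t0) + mean(sc[!lb] < t0) - 1
  expect_lt(j, 0.1)
})

test_that("performance measures derive exactly from confusion counts", {
  # printed contingency-table fixture: pure arithmetic identity
  m <- performance_measures(tn = 135, fp = 31, fn = 8, tp = 24)
  expect_equal(m$sensitivity, 24 / 32)
  expect_equal(m$specificity, 135 / 166)
  expect_equal(m$npv, 135 / 143)
  expect_equal(m$ppv, 24 / 55)
  expect_equal(m$fpr, 1 - m$specificity)
  expect_equal(m$fnr, 1 - m$sensitivity)
  expect_equal(m$accuracy, 159 / 198)
})

test_that("training on separable data reaches AUC 1 and is deterministic", {
  cohort <- toy_cohort(10, sep = 4, seed = 10)
  sp <- split_by_subject(cohort, 8, min_lesions = 30, seed = 1)
  tr <- cohort[cohort$subject_id %in% sp$train_subjects, ]
  te <- cohort[cohort$subject_id %in% sp$test_subjects, ]
  fit <- train_prl_classifier(tr, smote_config(seed = 1), n_folds = 5,
                              n_trees = 150, seed = 11)
  perf <- evaluate_classifier(fit, te)
  expect_equal(perf$auc, 1)
  expect_equal(unname(perf$confusion["fn"] + perf$confusion["fp"]), 0L)
  # all eight measures reproduce from the counts
  cm <- perf$confusion
  expect_equal(perf$measures,
               performance_measures(cm["tn"], cm["fp"], cm["fn"], cm["tp"]),
               ignore_attr = TRUE)
  fit2 <- train_prl_classifier(tr, smote_config(seed = 1), n_folds = 5,
                               n_trees = 150, seed = 11)
  expect_identical(predict(fit, te), predict(fit2, te))
  expect_error(train_prl_classifier(tr[!tr$is_prl_truth, ]), "both classes")
})

test_that("label-permuted training yields chance-level held-out AUC", {
  set.seed(12)
  aucs <- replicate(8, {
    cohort <- toy_cohort(8, per_subject = 40, sep = 3,
                         seed = sample.int(1e6, 1))
    cohort$is_prl_truth <- sample(cohort$is_prl_truth)
    sp <- split_by_subject(cohort, 6, min_lesions = 40,
                           seed = sample.int(1e6, 1))
    tr <- cohort[cohort$subject_id %in% sp$train_subjects, ]
    te <- cohort[cohort$subject_id %in% sp$test_subjects, ]
    fit <- train_prl_classifier(tr, smote_config(seed = 1), n_folds = 3,
                                n_trees = 100, tune = FALSE,
                                seed = sample.int(1e6, 1))
    evaluate_classifier(fit, te)$auc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("permutation importance separates signal from noise features", {
  cohort <- toy_cohort(10, per_subject = 50, sep = 4, seed = 13)
  sp <- split_by_subject(cohort, 8, min_lesions = 50, seed = 2)
  tr <- cohort[cohort$subject_id %in% sp$train_subjects, ]
  te <- cohort[cohort$subject_id %in% sp$test_subjects, ]
  fit <- train_prl_classifier(tr, smote_config(seed = 1), n_folds = 5,
                              n_trees = 200, tune = FALSE, seed = 3)
  imp <- permutation_importance(fit, te, n_rep = 10, seed = 4)
  expect_setequal(imp$feature, c("f1", "f2", "f3"))
  noise <- imp$raw_importance[imp$feature == "f3"]
  expect_lt(abs(noise), 10)
  expect_true(all(imp$raw_importance[imp$feature != "f3"] > noise))
})

test_that("resampling CIs: degenerate percentiles and reproducibility", {
  cohort <- toy_cohort(10, per_subject = 40, sep = 4, seed = 14)
  ci <- resample_ci(cohort, n_iter = 2, n_train_subjects = 8,
                    min_lesions = 40, n_folds = 3, n_trees = 100,
                    tune = FALSE, seed = 6)
  expect_equal(nrow(ci$replicates), 2)
  a <- ci$replicates$auc
  row <- ci$ci[ci$ci$measure == "auc", ]
  expect_equal(row$ci_low, min(a))    # two replicates: empirical percentiles
  expect_equal(row$ci_high, max(a))   # degenerate to min/max
  ci2 <- resample_ci(cohort, n_iter = 2, n_train_subjects = 8,
                     min_lesions = 40, n_folds = 3, n_trees = 100,
                     tune = FALSE, seed = 6)
  expect_identical(ci$replicates, ci2$replicates)
})

test_that("broom-style and plot methods produce well-formed output", {
  cohort <- toy_cohort(8, sep = 4, seed = 15)
  sp <- split_by_subject(cohort, 6, min_lesions = 30, seed = 1)
  tr <- cohort[cohort$subject_id %in% sp$train_subjects, ]
  te <- cohort[cohort$subject_id %in% sp$test_subjects, ]
  fit <- train_prl_classifier(tr, smote_config(seed = 1), n_folds = 3,
                              n_trees = 100, seed = 2)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(all(c("mtry", "cv_auc") %in% names(tidy(fit))))
  expect_equal(nrow(glance(fit)), 1)
  perf <- evaluate_classifier(fit, te)
  td <- tidy(perf)
  expect_equal(nrow(td), 9)
  expect_s3_class(autoplot(perf), "ggplot")
  imp <- permutation_importance(fit, te, n_rep = 3, seed = 1)
  expect_s3_class(plot_importance(imp), "ggplot")
})
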