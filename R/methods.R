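#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the cross-validation trace of a PRL classifier
#'
#' @param x A `prl_classifier`.
#' @param ... Unused.
#' @return Tibble of `mtry` candidates and their out-of-fold AUC (one row
#'   with the chosen `mtry` when tuning was off).
#' @export
tidy.prl_classifier <- function(x, ...) {
  if (!is.null(x$cv)) return(x$cv)
  tibble::tibble(mtry = x$mtry, cv_auc = NA_real_)
}

#' One-row summary of a PRL classifier
#'
#' @param x A `prl_classifier`.
#' @param ... Unused.
#' @return Tibble with the chosen `mtry`, forest size, training rows and
#'   best cross-validated AUC.
#' @export
glance.prl_classifier <- function(x, ...) {
  tibble::tibble(mtry = x$mtry, n_trees = x$n_trees, n_train = x$n_train,
                 cv_auc = if (!is.null(x$cv)) max(x$cv$cv_auc) else NA_real_)
}

#' @export
print.prl_classifier <- function(x, ...) {
  cat(sprintf("PRL random-forest classifier: %d trees, mtry %d, %d features\n",
              x$n_trees, x$mtry, length(x$feature_names)))
  if (!is.null(x$cv)) {
    cat(sprintf("  cross-validated AUC: %.3f\n", max(x$cv$cv_auc)))
  }
  invisible(x)
}

#' Tidy a performance report into one row per measure
#'
#' @param x A `prl_performance`.
#' @param ... Unused.
#' @return Tibble: `measure`, `value`.
#' @export
tidy.prl_performance <- function(x, ...) {
  m <- x$measures
  tibble::tibble(
    measure = c("auc", "threshold", "accuracy", "ppv", "npv", "fpr", "fnr",
                "sensitivity", "specificity"),
    value = c(x$auc, x$threshold, m$accuracy, m$ppv, m$npv, m$fpr, m$fnr,
              m$sensitivity, m$specificity))
}

#' One-row summary of a performance report
#'
#' @param x A `prl_performance`.
#' @param ... Unused.
#' @return One-row tibble: AUC, threshold, confusion counts and the eight
#'   derived measures.
#' @export
glance.prl_performance <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(auc = x$auc, threshold = x$threshold),
                   x$measures)
}

#' @export
print.prl_performance <- function(x, ...) {
  subset_note <- if (isTRUE(x$exclude_confluent)) " (non-confluent subset)" else ""
  cat(sprintf("PRL classification performance%s on %d lesions\n", subset_note, x$n))
  cat(sprintf("  AUC %.3f at Youden threshold %.3f\n", x$auc, x$threshold))
  cat(sprintf("  confusion (tn fp fn tp): %d %d %d %d\n",
              x$confusion["tn"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tp"]))
  m <- x$measures
  cat(sprintf("  sens %.3f  spec %.3f  ppv %.3f  npv %.3f  acc %.3f\n",
              m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy))
  invisible(x)
}

#' ROC curve of a performance report
#'
#' @param object A `prl_performance`.
#' @param ... Unused.
#' @return A ggplot: ROC curve with the Youden operating point marked.
#' @export
autoplot.prl_performance <- function(object, ...) {
  scores <- object$scores; y <- object$labels
  cand <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- purrr::map_dfr(cand, function(t) {
    tibble::tibble(fpr = sum(!y & scores >= t) / sum(!y),
                   tpr = sum(y & scores >= t) / sum(y))
  })
  op <- tibble::tibble(
    fpr = sum(!y & scores >= object$threshold) / sum(!y),
    tpr = sum(y & scores >= object$threshold) / sum(y))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = op, colour = "red", size = 2) +
    ggplot2::labs(x = "False positive rate", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.2f)", object$auc),
                  subtitle = sprintf("Youden threshold %.3f", object$threshold)) +
    ggplot2::theme_minimal()
}

#' Bar chart of permutation variable importance
#'
#' @param importance Importance tibble from [permutation_importance()].
#' @param top_n Number of features to show.
#' @return A ggplot.
#' @export
plot_importance <- function(importance, top_n = 15) {
  dat <- utils::head(importance, top_n)
  dat$feature <- stats::reorder(dat$feature, dat$raw_importance)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$raw_importance,
                                    y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% increase in MSE after permutation", y = NULL,
                  title = "Permutation variable importance") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
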