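#' Names of the 44 first-order radiomic features
#'
#' The roster summarizes a lesion's phase intensities in three ways:
#' location/spread of the intensities (22 features), shape of their
#' distribution (9), and magnitude/diversity (13). Empirical probabilities
#' `p(x)` behind uniformity and entropy are relative frequencies of exact
#' distinct intensity values - no binning is applied. The printed-formula
#' features (mean, interquartile range, variance, skew, energy, uniformity,
#' entropy) use population (1/n) normalization and log base 2 exactly as
#' defined.
#'
#' @return Character vector of the 44 feature column names, in table order.
#' @export
prl_feature_names <- function() {
  c(
    # location / spread
    "mean", "median", "mode", "minimum", "maximum", "range",
    "interquartile_range", "midrange",
    "p05", "p10", "p20", "p25", "p30", "p40",
    "p60", "p70", "p75", "p80", "p90", "p95",
    "interdecile_range", "trimmed_mean_10",
    # distribution shape
    "variance", "standard_deviation", "mean_absolute_deviation",
    "robust_mean_absolute_deviation", "median_absolute_deviation",
    "skewness", "kurtosis", "excess_kurtosis", "quartile_skewness",
    # magnitude / diversity
    "energy", "total_energy", "mean_energy", "root_mean_square",
    "sum", "sum_absolute", "max_absolute", "min_absolute",
    "uniformity", "entropy", "normalized_entropy",
    "distinct_value_fraction", "coefficient_of_variation")
}

#' First-order radiomic features of one intensity sample
#'
#' Computes the 44 first-order statistics for the phase intensities of one
#' lesion. Conventions: population (1/n) moments; `sd = sqrt(variance)`;
#' skewness and kurtosis (and their derived forms) are 0 for a constant
#' sample; empirical probabilities use exact value equality with no
#' binning; entropy uses log base 2; quantiles are R's default (type 7).
#' Ratio features guard a zero denominator by returning 0, and the robust
#' mean absolute deviation is 0 when no sample value falls inside the
#' 10th-90th percentile window (possible only for very small samples).
#'
#' @param values Numeric vector of voxel intensities (length >= 1, finite).
#' @param voxel_volume_mm3 Voxel volume used for `total_energy`.
#' @param bin_width Optional width for discretizing intensities before
#'   computing the empirical distribution behind mode, uniformity, entropy
#'   and the distinct-value fraction (sensitivity analyses only; the
#'   default `NULL` uses exact values, i.e. no binning).
#' @return A one-row tibble with the 44 feature columns of
#'   [prl_feature_names()].
#' @export
extract_features <- function(values, voxel_volume_mm3 = 1, bin_width = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 1L) stop("empty intensity sample")
  if (!all(is.finite(x))) stop("intensity sample contains non-finite values")

  mu <- sum(x) / n
  q <- stats::quantile(x, c(.05, .10, .20, .25, .30, .40, .50,
                            .60, .70, .75, .80, .90, .95), names = FALSE)
  med <- q[7]
  v <- sum((x - mu)^2) / n
  sdev <- sqrt(v)
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  skew <- if (sdev > 0) m3 / sdev^3 else 0
  kurt <- if (sdev > 0) m4 / sdev^4 else 0
  exkurt <- if (sdev > 0) kurt - 3 else 0
  iqr_den <- q[10] - q[4]
  qskew <- if (iqr_den > 0) (q[4] + q[10] - 2 * med) / iqr_den else 0
  rob <- x[x >= q[2] & x <= q[12]]
  # tiny samples can have no values inside the 10-90 percentile window
  rob_mad <- if (length(rob) > 0) mean(abs(rob - mean(rob))) else 0

  # empirical distribution over exact distinct values (no binning unless a
  # bin width is requested explicitly)
  xb <- if (is.null(bin_width)) x else round(x / bin_width) * bin_width
  ux <- xb[!duplicated(xb)]
  cnt <- tabulate(match(xb, ux), nbins = length(ux))
  p <- cnt / n
  uniformity <- sum(p^2)
  entropy <- -sum(p * log2(p))

  energy <- sum(x^2)
  mn <- min(x); mx <- max(x)

  tibble::tibble(
    mean = mu, median = med,
    mode = min(ux[cnt == max(cnt)]),
    minimum = mn, maximum = mx, range = mx - mn,
    interquartile_range = abs(q[10] - q[4]), midrange = (mn + mx) / 2,
    p05 = q[1], p10 = q[2], p20 = q[3], p25 = q[4], p30 = q[5], p40 = q[6],
    p60 = q[8], p70 = q[9], p75 = q[10], p80 = q[11], p90 = q[12], p95 = q[13],
    interdecile_range = q[12] - q[2],
    trimmed_mean_10 = mean(x, trim = 0.1),
    variance = v, standard_deviation = sdev,
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mean_absolute_deviation = rob_mad,
    median_absolute_deviation = stats::median(abs(x - med)),
    skewness = skew, kurtosis = kurt, excess_kurtosis = exkurt,
    quartile_skewness = qskew,
    energy = energy, total_energy = energy * voxel_volume_mm3,
    mean_energy = energy / n, root_mean_square = sqrt(energy / n),
    sum = sum(x), sum_absolute = sum(abs(x)),
    max_absolute = max(abs(x)), min_absolute = min(abs(x)),
    uniformity = uniformity, entropy = entropy,
    normalized_entropy = if (n > 1) entropy / log2(n) else 0,
    distinct_value_fraction = length(cnt) / n,
    coefficient_of_variation = if (mu != 0) sdev / mu else 0)
}

#' Per-lesion feature table
#'
#' One row per labelled lesion, computed over that lesion's voxels in the
#' final (dilated, tissue-excluded) label map.
#'
#' @param phase Phase volume.
#' @param labels Lesion label array on the same grid.
#' @param records Optional lesion records (from [label_lesions()]); when
#'   given, `subject_id`, `is_confluent` and `is_prl_truth` are joined in
#'   and every record id must exist in the label map.
#' @param include_size Append the lesion voxel count as a `size_vox`
#'   feature column.
#' @param bin_width Passed through to [extract_features()].
#' @return Tibble keyed by (`subject_id`, `lesion_id`) with the 44 feature
#'   columns, optional `size_vox`, and label columns when `records` is
#'   supplied.
#' @export
extract_feature_table <- function(phase, labels, records = NULL,
                                  include_size = FALSE, bin_width = NULL) {
  stop_if_grid_mismatch(phase, labels, call_name = "extract_feature_table")
  K <- max(labels)
  if (K < 1) stop("label map contains no lesions")
  vv <- voxel_size(phase)^3
  in_les <- labels > 0
  vals <- split(as.numeric(phase[in_les]), as.integer(labels[in_les]))
  present <- as.integer(names(vals))
  if (!is.null(records) && !all(records$lesion_id %in% present)) {
    missing_ids <- setdiff(records$lesion_id, present)
    stop(sprintf("lesion record id(s) absent from label map: %s",
                 paste(missing_ids, collapse = ", ")))
  }
  feats <- purrr::map(vals, extract_features, voxel_volume_mm3 = vv,
                      bin_width = bin_width)
  tab <- dplyr::bind_rows(feats)
  tab <- dplyr::bind_cols(tibble::tibble(lesion_id = present), tab)
  if (include_size) {
    tab$size_vox <- unname(vapply(vals, length, integer(1)))
  }
  if (!is.null(records)) {
    tab <- dplyr::inner_join(
      records[, c("subject_id", "lesion_id", "is_confluent", "is_prl_truth")],
      tab, by = "lesion_id")
    tab <- dplyr::relocate(tab, "is_confluent", "is_prl_truth",
                           .after = dplyr::last_col())
  }
  tibble::as_tibble(tab)
}
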