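# Independent reference implementations used as oracles. Each is written
# directly from the defining formula or as an exhaustive computation, kept
# deliberately separate from the package internals.

# First-order features, one expression per formula.
oracle_features <- function(x, voxel_volume_mm3 = 1) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  q <- function(p) unname(quantile(x, p, type = 7))
  ux <- unique(x)
  p_emp <- vapply(ux, function(u) sum(x == u) / n, numeric(1))
  med <- q(.5)
  rob <- x[x >= q(.1) & x <= q(.9)]
  list(
    mean = mu,
    median = med,
    mode = min(ux[vapply(ux, function(u) sum(x == u), numeric(1)) ==
                    max(vapply(ux, function(u) sum(x == u), numeric(1)))]),
    minimum = min(x), maximum = max(x), range = max(x) - min(x),
    interquartile_range = abs(q(.75) - q(.25)),
    midrange = (min(x) + max(x)) / 2,
    p05 = q(.05), p10 = q(.10), p20 = q(.20), p25 = q(.25), p30 = q(.30),
    p40 = q(.40), p60 = q(.60), p70 = q(.70), p75 = q(.75), p80 = q(.80),
    p90 = q(.90), p95 = q(.95),
    interdecile_range = q(.9) - q(.1),
    trimmed_mean_10 = mean(x, trim = 0.1),
    variance = v,
    standard_deviation = s,
    mean_absolute_deviation = sum(abs(x - mu)) / n,
    robust_mean_absolute_deviation = if (length(rob) == 0) 0 else
      sum(abs(rob - mean(rob))) / length(rob),
    median_absolute_deviation = median(abs(x - med)),
    skewness = if (s == 0) 0 else (sum((x - mu)^3) / n) / s^3,
    kurtosis = if (s == 0) 0 else (sum((x - mu)^4) / n) / s^4,
    excess_kurtosis = if (s == 0) 0 else (sum((x - mu)^4) / n) / s^4 - 3,
    quartile_skewness = if (q(.75) == q(.25)) 0 else
      (q(.25) + q(.75) - 2 * med) / (q(.75) - q(.25)),
    energy = sum(x^2),
    total_energy = sum(x^2) * voxel_volume_mm3,
    mean_energy = sum(x^2) / n,
    root_mean_square = sqrt(sum(x^2) / n),
    sum = sum(x),
    sum_absolute = sum(abs(x)),
    max_absolute = max(abs(x)),
    min_absolute = min(abs(x)),
    uniformity = sum(p_emp^2),
    entropy = sum(-p_emp * log2(p_emp)),
    normalized_entropy = if (n == 1) 0 else sum(-p_emp * log2(p_emp)) / log2(n),
    distinct_value_fraction = length(ux) / n,
    coefficient_of_variation = if (mu == 0) 0 else s / mu)
}

# Exhaustive nearest-centre-voxel assignment (ties -> smaller label).
oracle_nn_assign <- function(mask, centers) {
  d <- dim(mask)
  midx <- which(mask != 0)
  cidx <- which(centers > 0)
  cl <- as.integer(centers[cidx])
  cco <- arrayInd(cidx, d)
  mco <- arrayInd(midx, d)
  out <- integer(length(midx))
  for (i in seq_along(midx)) {
    d2 <- (cco[, 1] - mco[i, 1])^2 + (cco[, 2] - mco[i, 2])^2 +
          (cco[, 3] - mco[i, 3])^2
    out[i] <- min(cl[d2 == min(d2)])
  }
  out
}

# Exhaustive Youden-J scan over all distinct scores (ties -> smallest t).
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    if (j > best_j) { best_j <- j; best_t <- t }
  }
  best_t
}

# O(n^2) pairwise AUC (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive k nearest minority neighbours of each minority row; returns a
# list of index sets including all rows tied with the k-th distance.
oracle_knn_sets <- function(minority, k, tol = 1e-9) {
  n <- nrow(minority)
  lapply(seq_len(n), function(i) {
    d2 <- colSums((t(minority) - minority[i, ])^2)
    d2[i] <- Inf
    kth <- sort(d2)[k]
    which(d2 <= kth + tol)
  })
}

# Local maxima of a smoothed field by exhaustive 26-neighbourhood
# comparison (strictly greater than every in-bounds neighbour).
oracle_local_maxima <- function(field) {
  d <- dim(field)
  out <- array(FALSE, d)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    nb <- field[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    if (field[i, j, k] > max(nb[-14])) out[i, j, k] <- TRUE
  }
  out
}
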