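mk <- function(d = c(8, 8, 8), idx = NULL, vs = 1) {
  a <- array(0, d)
  if (!is.null(idx)) a[idx] <- 1
  as_volume(a, vs)
}

test_that("Dice coefficient handles identity, disjoint, partial and empty", {
  a <- mk(idx = 1:8); b <- mk(idx = 9:16)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  ov <- mk(idx = 5:12)   # |A|=|B|=8, overlap 4 -> 2*4/16
  expect_equal(dice(a, ov), 0.5)
  expect_equal(dice(mk(), mk()), 0)
})

test_that("binarize applies the >= convention", {
  p <- mk(); p[2, 2, 2] <- 0.9; p[3, 3, 3] <- 0.5
  b <- binarize(p, 0.5)
  expect_equal(sum(b), 2)          # boundary value included
  expect_equal(sum(binarize(mk(), 0.5)), 0)
  expect_true(b[2, 2, 2] == 1 && b[3, 3, 3] == 1)
})

test_that("threshold selection maximizes Dice, ties to the smallest", {
  gold <- mk(idx = 10:30)
  # prob equal to gold: every threshold gives Dice 1 -> smallest wins
  expect_equal(select_threshold(gold, gold, c(0.25, 0.5, 0.75)), 0.25)
  # empty gold: all Dice 0 -> smallest wins
  p <- mk(); p[4, 4, 4] <- 0.8
  expect_equal(select_threshold(p, mk(), c(0.3, 0.6, 0.9)), 0.3)
  expect_error(select_threshold(p, mk(), numeric(0)), "empty")
  expect_error(select_threshold(p, mk(), c(0.5, 0.4)), "increasing")
})

test_that("selected threshold equals an exhaustive Dice sweep on a phantom", {
  cs <- generate_case(small_spec(seed = 21, prob_blur_sigma_vox = 1))
  grid <- seq(0.05, 0.95, by = 0.05)
  sel <- select_threshold(cs$prob_map, cs$gold_mask, grid)
  scores <- sapply(grid, function(t) dice(binarize(cs$prob_map, t), cs$gold_mask))
  expect_equal(sel, grid[which.max(scores)])
})

test_that("box dilation: 27-voxel interior case, corner clipping, superset", {
  single <- mk(idx = NULL); single[4, 4, 4] <- 1
  expect_equal(sum(dilate_one_voxel(single)), 27)
  corner <- mk(); corner[1, 1, 1] <- 1
  expect_equal(sum(dilate_one_voxel(corner)), 8)
  expect_equal(sum(dilate_one_voxel(mk())), 0)
  set.seed(1)
  rnd <- mk(idx = sample(512, 60))
  dil <- dilate_one_voxel(rnd)
  expect_true(all(dil[rnd == 1] == 1))
})

test_that("tissue exclusion removes only newly dilated voxels", {
  orig <- mk(); orig[4, 4, 4] <- 1
  dil <- dilate_one_voxel(orig)
  ring <- dil - orig
  expect_equal(as.numeric(exclude_tissue(dil, orig, mk(), mk())),
               as.numeric(dil))
  expect_equal(as.numeric(exclude_tissue(dil, orig, ring, mk())),
               as.numeric(orig))
  # CSF over the original voxel must not remove it
  expect_equal(as.numeric(exclude_tissue(dil, orig, orig, mk())),
               as.numeric(dil))
  expect_error(exclude_tissue(orig, dil, mk(), mk()), "subset")
})

gauss_blob <- function(d, ctr, sigma = 2) {
  co <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  array(exp(-rowSums(sweep(co, 2, ctr)^2) / (2 * sigma^2)), d)
}

test_that("centre detection finds isolated and paired blobs", {
  d <- c(24, 24, 24)
  one <- as_volume(gauss_blob(d, c(12, 12, 12)), 1)
  mask <- as_volume((one > 0.1) + 0, 1)
  ct <- detect_centers(one, mask, 1)
  expect_equal(max(ct), 1)
  expect_true(ct[12, 12, 12] == 1)

  two <- as_volume(gauss_blob(d, c(7, 7, 7)) + gauss_blob(d, c(17, 17, 17)), 1)
  mask2 <- as_volume((two > 0.1) + 0, 1)
  ct2 <- detect_centers(two, mask2, 1)
  expect_equal(max(ct2), 2)
  # label 1 belongs to the lexicographically first component
  expect_equal(ct2[7, 7, 7], 1)
  expect_equal(ct2[17, 17, 17], 2)
})

test_that("touching blobs with separated peaks match the local-maxima oracle", {
  d <- c(26, 26, 26)
  f <- gauss_blob(d, c(9, 13, 13), sigma = 2) +
       gauss_blob(d, c(17, 13, 13), sigma = 2)
  prob <- as_volume(f / max(f), 1)
  mask <- as_volume((prob > 0.05) + 0, 1)
  expect_equal(max(aprl:::connected_components(mask != 0)), 1)  # supports touch
  ct <- detect_centers(prob, mask, 1)
  sm <- aprl:::gaussian_smooth(array(as.numeric(prob), d), 1)
  peaks <- which(oracle_local_maxima(sm) & mask != 0)
  expect_equal(max(ct), length(peaks))  # 2 centres
  expect_true(all(ct[peaks] > 0))       # each peak sits inside a centre
})

test_that("centre detection falls back to the probability argmax", {
  # a constant field has zero Hessian everywhere: no voxel qualifies
  d <- c(8, 8, 8)
  flat <- as_volume(array(0, d), 1)
  mask <- mk(d); mask[3:5, 3:5, 3:5] <- 1
  ct <- detect_centers(flat, mask, 1)
  expect_equal(max(ct), 1)
  expect_equal(sum(ct > 0), 1)
})

test_that("nearest-neighbour assignment: identity, tie rule, oracle", {
  d <- c(12, 12, 12)
  ctr <- array(0L, d); ctr[3, 3, 3] <- 1L
  mask <- mk(d); mask[2:4, 2:4, 2:4] <- 1
  lab <- assign_labels_nn(mask, as_volume(ctr, 1))
  expect_true(all(lab[mask == 1] == 1))
  expect_equal(sum(lab > 0), sum(mask))

  # voxel equidistant between two centres takes the smaller label
  ctr2 <- array(0L, d); ctr2[4, 6, 6] <- 1L; ctr2[8, 6, 6] <- 2L
  m2 <- mk(d); m2[4, 6, 6] <- m2[8, 6, 6] <- m2[6, 6, 6] <- 1
  lab2 <- assign_labels_nn(m2, as_volume(ctr2, 1))
  expect_equal(lab2[6, 6, 6], 1L)

  set.seed(42)
  for (rep in 1:5) {
    mask3 <- mk(d, idx = sample(prod(d), 400))
    ctr3 <- array(0L, d)
    cvox <- sample(which(mask3 == 1), 12)
    ctr3[cvox] <- rep(1:3, each = 4)
    lab3 <- assign_labels_nn(mask3, as_volume(ctr3, 1))
    expect_equal(as.integer(lab3[mask3 == 1]),
                 oracle_nn_assign(mask3, ctr3))
  }
})

test_that("adding a disjoint lesion never relabels existing voxels", {
  d <- c(20, 20, 20)
  mask <- mk(d); mask[3:6, 3:6, 3:6] <- 1
  ctr <- array(0L, d); ctr[4, 4, 4] <- 1L
  base <- assign_labels_nn(mask, as_volume(ctr, 1))
  mask2 <- mask; mask2[14:17, 14:17, 14:17] <- 1
  ctr2 <- ctr; ctr2[15, 15, 15] <- 2L
  ext <- assign_labels_nn(mask2, as_volume(ctr2, 1))
  expect_true(all(ext[mask == 1] == base[mask == 1]))
})

test_that("confluence flags follow the shared-component rule", {
  d <- c(16, 16, 16)
  lab <- array(0L, d)
  lab[2:4, 2:4, 2:4] <- 1L; lab[10:12, 10:12, 10:12] <- 2L
  expect_equal(flag_confluent(as_volume(lab, 1)), c(FALSE, FALSE))
  lab2 <- array(0L, d)
  lab2[2:4, 2:4, 2:4] <- 1L; lab2[5:7, 2:4, 2:4] <- 2L  # touching
  expect_equal(flag_confluent(as_volume(lab2, 1)), c(TRUE, TRUE))
  lab3 <- lab2; lab3[12:14, 12:14, 12:14] <- 3L
  expect_equal(flag_confluent(as_volume(lab3, 1)), c(TRUE, TRUE, FALSE))
})

test_that("PRL status transfers by any overlap with the annotation", {
  d <- c(16, 16, 16)
  lab <- array(0L, d)
  lab[2:4, 2:4, 2:4] <- 1L; lab[6:8, 2:4, 2:4] <- 2L; lab[12:14, 2:4, 2:4] <- 3L
  lab <- as_volume(lab, 1)
  expect_equal(assign_prl_status(lab, mk(d)), c(FALSE, FALSE, FALSE))
  ann <- mk(d); ann[13, 3, 3] <- 1
  expect_equal(assign_prl_status(lab, ann), c(FALSE, FALSE, TRUE))
  straddle <- mk(d); straddle[3:7, 3, 3] <- 1  # crosses lesions 1 and 2
  expect_equal(assign_prl_status(lab, straddle), c(TRUE, TRUE, FALSE))
})

test_that("full labelling recovers phantom lesions and their PRL status", {
  cs <- generate_case(small_spec(seed = 31, n_lesions = 5, rim_fraction = 0.2))
  res <- label_lesions(cs$prob_map, cs$gold_mask, cs$csf_mask, cs$gm_mask,
                       cs$prl_annotation, subject_id = "P1")
  expect_equal(nrow(res$records), 5)
  expect_equal(sum(res$records$is_prl_truth), 1)
  expect_false(any(res$records$is_confluent))
  # partition property: sizes sum to the final mask support
  seg <- binarize(cs$prob_map, res$threshold)
  final <- exclude_tissue(dilate_one_voxel(seg), seg, cs$csf_mask, cs$gm_mask)
  expect_equal(sum(res$records$size_vox), sum(final))
  expect_equal(sum(res$labels > 0), sum(final))
  # support identity: label support equals original + allowed ring exactly
  expect_true(all((res$labels > 0) == (final != 0)))
})

test_that("confluent phantom pairs are flagged by the pipeline", {
  cs <- generate_case(small_spec(seed = 32, n_lesions = 6,
                                 confluence_rate = 1 / 3))
  res <- label_lesions(cs$prob_map, cs$gold_mask, cs$csf_mask, cs$gm_mask,
                       cs$prl_annotation)
  expect_gte(sum(res$records$is_confluent), 2)
})
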