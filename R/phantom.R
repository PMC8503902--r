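#' Phantom specification
#'
#' Parameters of the synthetic subject generator. The phantom emulates the
#' inputs the pipeline consumes: a zero-centred normalized phase volume with
#' ellipsoidal white-matter lesions, a hypointense shell on rim-positive
#' lesions, a smoothed-truth lesion probability map, CSF/grey-matter slabs
#' abutting a subset of lesions, and single-slice line annotations through
#' each rim lesion's centre along its longest in-plane axis.
#'
#' Defaults describe the emulated cohort: ~50 lesions per subject, 12%
#' rim-positive, rim contrast of minus two background standard deviations on
#' a shell 1.5 voxels thick, and rim lesions systematically larger (one
#' voxel of extra semi-axis) since PRLs tend to be larger than other
#' lesions.
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size_mm Isometric voxel edge, mm.
#' @param n_lesions Number of lesions per subject.
#' @param rim_fraction Fraction of lesions that are rim-positive.
#' @param lesion_radius_range_vox Min/max ellipsoid semi-axis, voxels.
#' @param rim_thickness_vox Thickness of the hypointense shell, voxels.
#' @param rim_contrast Mean additive offset of shell intensities
#'   (normalized units; must be negative).
#' @param background_sd Standard deviation of normal-appearing tissue noise.
#' @param confluence_rate Fraction of lesions placed touching a partner.
#' @param prob_blur_sigma_vox Gaussian sigma used to soften the truth mask
#'   into a probability map.
#' @param rim_radius_boost Extra semi-axis length (voxels) given to
#'   rim-positive lesions.
#' @param interior_offset_range Range of the non-negative iso/hyperintense
#'   offset applied to lesion interiors.
#' @param rim_strength_range Per-lesion multiplier range on `rim_contrast`;
#'   centred on 1 so the mean shell offset across lesions equals
#'   `rim_contrast`, while individual rims vary from faint to pronounced.
#' @param rim_coverage_range Range of the fraction of the shell carrying
#'   the rim offset; rims on phase images are often incomplete rings, so
#'   coverage below 1 removes a contiguous angular cap.
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(72L, 72L, 72L),
                         voxel_size_mm = 0.65,
                         n_lesions = 50L,
                         rim_fraction = 0.12,
                         lesion_radius_range_vox = c(2.5, 4.5),
                         rim_thickness_vox = 1.5,
                         rim_contrast = -2,
                         background_sd = 1,
                         confluence_rate = 0.2,
                         prob_blur_sigma_vox = 1,
                         rim_radius_boost = 1,
                         interior_offset_range = c(0, 0.5),
                         rim_strength_range = c(0.25, 1.75),
                         rim_coverage_range = c(0.3, 1),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            voxel_size_mm > 0, n_lesions >= 1,
            rim_fraction >= 0, rim_fraction <= 1,
            length(lesion_radius_range_vox) == 2L,
            lesion_radius_range_vox[1] <= lesion_radius_range_vox[2],
            all(lesion_radius_range_vox > 0),
            rim_thickness_vox > 0, rim_contrast < 0, background_sd > 0,
            confluence_rate >= 0, confluence_rate <= 1,
            prob_blur_sigma_vox > 0, rim_radius_boost >= 0,
            interior_offset_range[1] >= 0,
            interior_offset_range[1] <= interior_offset_range[2],
            all(rim_strength_range > 0),
            rim_strength_range[1] <= rim_strength_range[2],
            rim_coverage_range[1] > 0, rim_coverage_range[2] <= 1,
            rim_coverage_range[1] <= rim_coverage_range[2])
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_lesions = as.integer(n_lesions), rim_fraction = rim_fraction,
    lesion_radius_range_vox = lesion_radius_range_vox,
    rim_thickness_vox = rim_thickness_vox, rim_contrast = rim_contrast,
    background_sd = background_sd, confluence_rate = confluence_rate,
    prob_blur_sigma_vox = prob_blur_sigma_vox,
    rim_radius_boost = rim_radius_boost,
    interior_offset_range = interior_offset_range,
    rim_strength_range = rim_strength_range,
    rim_coverage_range = rim_coverage_range,
    seed = as.integer(seed)), class = "phantom_spec")
}

# radius of the ellipsoid x' A x = 1 along unit direction u
ellipsoid_radius_along <- function(A, u) 1 / sqrt(drop(t(u) %*% A %*% u))

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# quadratic form q(x) = (x-c)' A (x-c) over the rows of coords
ellipsoid_q <- function(coords, center, R, semi_axes) {
  Y <- sweep(coords, 2, center) %*% R
  rowSums(sweep(Y, 2, semi_axes, "/")^2)
}

# voxel coordinates in the bounding box of an ellipsoid, clipped to the grid
bounding_coords <- function(center, radius, d) {
  lo <- pmax(1L, floor(center - radius - 1))
  hi <- pmin(d, ceiling(center + radius + 1))
  if (any(lo > hi)) return(NULL)
  as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
}

lin_index <- function(co, d) co[, 1] + (co[, 2] - 1) * d[1] + (co[, 3] - 1) * d[1] * d[2]

#' Generate one synthetic subject
#'
#' Fully deterministic given `spec$seed`. Background intensities are i.i.d.
#' normal(0, `background_sd`); each lesion is a randomly oriented ellipsoid
#' with a non-negative interior offset; rim lesions additionally carry an
#' inner shell of thickness `rim_thickness_vox` with mean offset
#' `rim_contrast`. A fraction `confluence_rate` of lesions is placed
#' touching a partner (at most one rim per pair). The probability map is
#' the truth mask blurred with a Gaussian and clipped to `[0, 1]`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_case` list with elements `phase`, `gold_mask`,
#'   `prob_map`, `csf_mask`, `gm_mask`, `prl_annotation`, `truth_labels`
#'   (per-voxel owning lesion id), `shell_mask`, and `truth` (a tibble with
#'   one row per lesion: centre, semi-axes, `is_rim`, `is_confluent_pair`).
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  rr <- spec$lesion_radius_range_vox
  max_r <- rr[2] + spec$rim_radius_boost
  if (any(d < 4 * max_r)) {
    stop("grid too small: each axis must be at least 4x the maximum lesion radius")
  }
  set.seed(spec$seed)
  n <- spec$n_lesions
  n_pairs <- min(floor(n / 2), round(spec$confluence_rate * n / 2))

  # rim assignment: at most one rim lesion per confluent pair
  n_rim <- round(spec$rim_fraction * n)
  pair_of <- rep(NA_integer_, n)
  if (n_pairs > 0) pair_of[seq_len(2 * n_pairs)] <- rep(seq_len(n_pairs), each = 2)
  is_rim <- rep(FALSE, n)
  for (i in sample.int(n)) {
    if (sum(is_rim) >= n_rim) break
    p <- pair_of[i]
    if (!is.na(p) && any(is_rim[which(pair_of == p)])) next
    is_rim[i] <- TRUE
  }

  semi <- matrix(stats::runif(3 * n, rr[1], rr[2]), ncol = 3)
  semi[is_rim, ] <- semi[is_rim, , drop = FALSE] + spec$rim_radius_boost
  rot <- lapply(seq_len(n), function(i) random_rotation())
  Amat <- lapply(seq_len(n), function(i) {
    R <- rot[[i]]
    R %*% diag(1 / semi[i, ]^2) %*% t(R)
  })

  margin <- max_r + 2
  sep_gap <- 3.5  # keeps distinct lesions disjoint even after 1-voxel dilation
  centers <- matrix(NA_real_, n, 3)
  max_sem <- apply(semi, 1, max)
  for (i in seq_len(n)) {
    placed <- FALSE
    partner_mode <- !is.na(pair_of[i]) && i %% 2 == 0  # even pair member touches odd one
    for (try in seq_len(500L)) {
      if (partner_mode) {
        j <- i - 1L
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        dd <- ellipsoid_radius_along(Amat[[j]], u) +
              ellipsoid_radius_along(Amat[[i]], u) - 1
        cand <- centers[j, ] + dd * u
      } else {
        cand <- stats::runif(3, margin, d - margin)
      }
      if (any(cand < 2) || any(cand > d - 1)) next
      ok <- TRUE
      for (j2 in seq_len(i - 1L)) {
        if (partner_mode && j2 == i - 1L) next
        if (sqrt(sum((cand - centers[j2, ])^2)) <
            max_sem[i] + max_sem[j2] + sep_gap) { ok <- FALSE; break }
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop(sprintf("phantom placement failed for lesion %d", i))
  }

  # rasterize: first-claim ownership for voxels inside several ellipsoids
  owner <- array(0L, d)
  shell <- array(FALSE, d)
  interior_offset <- stats::runif(n, spec$interior_offset_range[1],
                                  spec$interior_offset_range[2])
  rim_strength <- stats::runif(n, spec$rim_strength_range[1],
                               spec$rim_strength_range[2])
  rim_coverage <- stats::runif(n, spec$rim_coverage_range[1],
                               spec$rim_coverage_range[2])
  covered <- vector("list", n)
  phase <- array(stats::rnorm(prod(d), 0, spec$background_sd), d)
  for (i in seq_len(n)) {
    co <- bounding_coords(centers[i, ], max_sem[i], d)
    q <- ellipsoid_q(co, centers[i, ], rot[[i]], semi[i, ])
    inside <- q <= 1
    if (!any(inside)) stop(sprintf("degenerate rasterization for lesion %d", i))
    lin <- lin_index(co[inside, , drop = FALSE], d)
    new <- lin[owner[lin] == 0L]
    owner[new] <- i
    if (is_rim[i]) {
      a_in <- pmax(semi[i, ] - spec$rim_thickness_vox, 0.5)
      q_in <- ellipsoid_q(co[inside, , drop = FALSE], centers[i, ], rot[[i]], a_in)
      shell_co <- co[inside, , drop = FALSE][q_in > 1, , drop = FALSE]
      shell_lin <- lin[q_in > 1]
      own <- owner[shell_lin] == i
      shell_co <- shell_co[own, , drop = FALSE]
      shell_lin <- shell_lin[own]
      shell[shell_lin] <- TRUE
      # incomplete rim: drop a contiguous angular cap so only a fraction
      # rim_coverage of the shell carries the hypointense offset
      w <- stats::rnorm(3); w <- w / sqrt(sum(w^2))
      proj <- sweep(shell_co, 2, centers[i, ]) %*% w
      keep <- proj <= stats::quantile(proj, rim_coverage[i], names = FALSE)
      covered[[i]] <- shell_lin[keep]
    }
  }
  for (i in seq_len(n)) {
    vox <- which(owner == i)
    phase[vox] <- phase[vox] + interior_offset[i]
    if (is_rim[i]) {
      sv <- covered[[i]]
      phase[sv] <- phase[sv] - interior_offset[i] +
        spec$rim_contrast * rim_strength[i]
    }
  }
  gold <- owner > 0L

  prob <- gaussian_smooth(gold + 0, spec$prob_blur_sigma_vox)
  prob[prob < 0] <- 0; prob[prob > 1] <- 1

  # CSF / GM slabs: half of the one-voxel ring around a subset of lesions
  csf <- array(FALSE, d); gm <- array(FALSE, d)
  n_slab <- max(1L, round(0.3 * n))
  slab_les <- sample.int(n, min(2L * n_slab, n))
  for (s in seq_along(slab_les)) {
    i <- slab_les[s]
    les <- owner == i
    ring <- dilate_one_voxel(les) & !gold
    ax <- sample.int(3, 1); sgn <- sample(c(-1, 1), 1)
    co <- arrayInd(which(ring), d)
    keep <- sgn * (co[, ax] - centers[i, ax]) > 0
    tgt <- lin_index(co[keep, , drop = FALSE], d)
    if (s <= n_slab) csf[tgt] <- TRUE else gm[tgt] <- TRUE
  }
  gm <- gm & !csf

  # annotation: 1-voxel line on the central axial slice of each rim lesion,
  # along the longest in-plane axis of the ellipsoid's cross-section
  annot <- array(FALSE, d)
  for (i in which(is_rim)) {
    z0 <- round(centers[i, 3])
    A2 <- Amat[[i]][1:2, 1:2]
    e <- eigen(A2, symmetric = TRUE)
    v <- e$vectors[, which.min(e$values)]
    L <- 1 / sqrt(min(e$values))
    t_seq <- seq(-L, L, by = 0.4)
    pts <- unique(cbind(round(centers[i, 1] + t_seq * v[1]),
                        round(centers[i, 2] + t_seq * v[2])))
    pts <- pts[pts[, 1] >= 1 & pts[, 1] <= d[1] &
               pts[, 2] >= 1 & pts[, 2] <= d[2], , drop = FALSE]
    lin <- pts[, 1] + (pts[, 2] - 1) * d[1] + (z0 - 1) * d[1] * d[2]
    lin <- lin[owner[lin] == i]
    if (length(lin) == 0L) {
      vox <- which(owner == i)
      co <- arrayInd(vox, d)
      dist2 <- rowSums(sweep(co, 2, centers[i, ])^2)
      lin <- vox[which.min(dist2)]
    }
    annot[lin] <- TRUE
  }

  vs <- spec$voxel_size_mm
  truth <- tibble::tibble(
    lesion_id = seq_len(n),
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    rx = semi[, 1], ry = semi[, 2], rz = semi[, 3],
    is_rim = is_rim,
    is_confluent_pair = !is.na(pair_of),
    rim_strength = ifelse(is_rim, rim_strength, NA_real_),
    rim_coverage = ifelse(is_rim, rim_coverage, NA_real_))
  structure(list(
    phase = as_volume(phase, vs),
    gold_mask = as_volume(gold + 0, vs),
    prob_map = as_volume(prob, vs),
    csf_mask = as_volume(csf + 0, vs),
    gm_mask = as_volume(gm + 0, vs),
    prl_annotation = as_volume(annot + 0, vs),
    truth_labels = as_volume(owner + 0, vs),
    shell_mask = as_volume(shell + 0, vs),
    truth = truth,
    spec = spec), class = "phantom_case")
}

#' Generate a cohort of synthetic subjects
#'
#' Subjects are independent; each draws its lesion count uniformly within
#' +/-30% of `spec$n_lesions` and uses a seed derived from `seed` and the
#' subject index, so any subject is reproducible in isolation.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [phantom_spec()] shared by all subjects.
#' @param seed Master seed for the cohort.
#' @return Named list of `phantom_case` objects (`S01`, `S02`, ...).
#' @export
generate_cohort <- function(n_subjects, spec, seed = spec$seed) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  lo <- max(1L, ceiling(0.7 * spec$n_lesions))
  hi <- floor(1.3 * spec$n_lesions)
  counts <- sample(lo:hi, n_subjects, replace = TRUE)
  seeds <- vapply(seq_len(n_subjects), function(i) derive_seed(seed, i), integer(1))
  cases <- lapply(seq_len(n_subjects), function(i) {
    sp <- spec
    sp$n_lesions <- counts[i]
    sp$seed <- seeds[i]
    generate_case(sp)
  })
  names(cases) <- sprintf("S%02d", seq_len(n_subjects))
  cases
}

#' Write a phantom case to a directory as NIfTI files + truth.csv
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$phase, file.path(dir, "phase.nii.gz"), "phase")
  write_volume(case$gold_mask, file.path(dir, "gold_mask.nii.gz"), "mask")
  write_volume(case$prob_map, file.path(dir, "prob_map.nii.gz"), "probability")
  write_volume(case$csf_mask, file.path(dir, "csf_mask.nii.gz"), "mask")
  write_volume(case$gm_mask, file.path(dir, "gm_mask.nii.gz"), "mask")
  write_volume(case$prl_annotation, file.path(dir, "prl_annotation.nii.gz"), "mask")
  utils::write.csv(case$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
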