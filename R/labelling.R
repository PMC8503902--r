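#' Sorensen-Dice coefficient of two binary masks
#'
#' Overlap measure `2 * |A & B| / (|A| + |B|)`, defined as 0 when both
#' masks are empty.
#'
#' @param a,b Binary masks on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, call_name = "dice")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(0)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Binarize a probability map
#'
#' Voxel is lesion iff probability `>= t` (boundary values included).
#'
#' @param prob Probability map.
#' @param t Threshold in `(0, 1)`.
#' @return Binary mask (0/1 array) on the same grid.
#' @export
binarize <- function(prob, t) {
  stopifnot(t > 0, t < 1)
  as_volume((prob >= t) + 0, voxel_size(prob))
}

#' Select the Dice-optimal binarization threshold
#'
#' Scans an increasing grid of candidate thresholds and returns the one
#' maximizing the Dice overlap between the binarized probability map and a
#' gold-standard lesion mask; ties break toward the smallest threshold.
#'
#' @param prob Probability map.
#' @param gold Gold-standard binary lesion mask (same grid).
#' @param thresholds Strictly increasing candidate thresholds in `(0, 1)`.
#' @return The selected threshold.
#' @export
select_threshold <- function(prob, gold, thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (length(thresholds) == 0) stop("empty threshold grid")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  stop_if_grid_mismatch(prob, gold, call_name = "select_threshold")
  scores <- vapply(thresholds, function(t) dice(binarize(prob, t), gold), numeric(1))
  thresholds[which.max(scores)]
}

#' Dilate a binary mask by one voxel in each direction
#'
#' Morphological dilation with the 3x3x3 box structuring element
#' (26-connectivity), clipped at the volume bounds. Output is always a
#' superset of the input.
#'
#' @param mask Binary mask.
#' @return Dilated binary mask.
#' @export
dilate_one_voxel <- function(mask) {
  m <- mask != 0
  out <- m
  offs <- neighbour_offsets(26)
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_array(m, offs[i, ], fill = FALSE)
  }
  if (is.numeric(mask)) out <- out + 0
  as_volume(array(out, dim(mask)), voxel_size(mask))
}

#' Mask CSF and grey matter out of voxels newly added by dilation
#'
#' Only voxels gained through dilation are subject to exclusion; original
#' lesion voxels are never removed, even where they overlap CSF/GM.
#'
#' @param dilated Dilated mask.
#' @param original Pre-dilation mask (`original` must be a subset of `dilated`).
#' @param csf,gm Binary tissue masks (may be empty).
#' @return `original | (dilated \ original \ csf \ gm)`.
#' @export
exclude_tissue <- function(dilated, original, csf, gm) {
  stop_if_grid_mismatch(dilated, original, csf, gm, call_name = "exclude_tissue")
  dil <- dilated != 0; org <- original != 0
  if (any(org & !dil)) stop("original mask is not a subset of the dilated mask")
  out <- org | (dil & !org & !(csf != 0) & !(gm != 0))
  as_volume(out + 0, voxel_size(dilated))
}

#' Detect distinct lesion centres from the probability map texture
#'
#' Smooths the probability map with a Gaussian, computes the 3x3 Hessian of
#' the smoothed field by central differences, and marks masked voxels whose
#' Hessian is negative definite (all three eigenvalues negative, i.e. local
#' peak-like texture). Connected components (26-connectivity) of marked
#' voxels are the centres, numbered 1..K by the lexicographic order of each
#' component's smallest voxel triple. If no voxel qualifies, the masked
#' voxel with the highest smoothed probability becomes the single centre.
#'
#' @param prob Probability map.
#' @param mask Binary lesion mask (nonempty).
#' @param smooth_sigma_vox Gaussian sigma in voxels.
#' @return Integer label array of centres (0 = background).
#' @export
detect_centers <- function(prob, mask, smooth_sigma_vox = 1) {
  stop_if_grid_mismatch(prob, mask, call_name = "detect_centers")
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  s <- gaussian_smooth(array(as.numeric(prob), dim(prob)), smooth_sigma_vox)
  d <- dim(s)
  ax_shift <- function(a, ax, o) {
    off <- c(0L, 0L, 0L); off[ax] <- o; shift_array(a, off)
  }
  # central-difference second derivatives (note shift moves content forward,
  # so content at +1 offset samples the voxel at x-1 and vice versa)
  h <- list()
  for (ax in 1:3) {
    h[[paste0(ax, ax)]] <- ax_shift(s, ax, 1L) + ax_shift(s, ax, -1L) - 2 * s
  }
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    h[[paste0(p[1], p[2])]] <-
      (ax_shift(ax_shift(s, p[1], 1L), p[2], 1L) +
       ax_shift(ax_shift(s, p[1], -1L), p[2], -1L) -
       ax_shift(ax_shift(s, p[1], 1L), p[2], -1L) -
       ax_shift(ax_shift(s, p[1], -1L), p[2], 1L)) / 4
  }
  # negative definiteness via Sylvester's criterion on -H:
  # h11 < 0, det of leading 2x2 > 0, det of full 3x3 < 0
  det2 <- h[["11"]] * h[["22"]] - h[["12"]]^2
  det3 <- h[["11"]] * (h[["22"]] * h[["33"]] - h[["23"]]^2) -
          h[["12"]] * (h[["12"]] * h[["33"]] - h[["23"]] * h[["13"]]) +
          h[["13"]] * (h[["12"]] * h[["23"]] - h[["22"]] * h[["13"]])
  marked <- (h[["11"]] < 0) & (det2 > 0) & (det3 < 0) & m
  # central differences are undefined on the outermost planes
  marked[c(1, d[1]), , ] <- FALSE
  marked[, c(1, d[2]), ] <- FALSE
  marked[, , c(1, d[3])] <- FALSE
  if (!any(marked)) {
    lab <- array(0L, d)
    masked_idx <- which(m)
    lab[masked_idx[which.max(s[masked_idx])]] <- 1L
    return(as_volume(lab, voxel_size(prob)))
  }
  lab <- renumber_lexicographic(connected_components(marked, 26))
  as_volume(lab, voxel_size(prob))
}

#' Assign every masked voxel to its nearest centre
#'
#' Nearest-neighbour label transfer: each masked voxel receives the label of
#' the centre component whose closest member voxel (Euclidean distance in
#' voxel units) is nearest; exact ties break toward the smaller label id.
#' Output support equals the mask exactly.
#'
#' @param mask Binary lesion mask.
#' @param centers Integer centre label array from [detect_centers()].
#' @return Integer lesion label array with support equal to `mask`.
#' @export
assign_labels_nn <- function(mask, centers) {
  stop_if_grid_mismatch(mask, centers, call_name = "assign_labels_nn")
  d <- dim(mask)
  m <- mask != 0
  K <- max(centers)
  if (K < 1) stop("no centers to assign from")
  idx <- which(m)
  if (length(idx) == 0L) return(as_volume(array(0L, d), voxel_size(mask)))
  co <- arrayInd(idx, d)
  cidx <- which(centers > 0)
  o <- order(centers[cidx], cidx)  # columns sorted by label: ties -> smaller id
  cidx <- cidx[o]
  clab <- as.integer(centers[cidx])
  cc <- arrayInd(cidx, d)
  best <- .nn_assign_cpp(co, cc, clab)
  lab <- array(0L, d)
  lab[idx] <- best
  as_volume(lab, voxel_size(mask))
}

#' Flag lesions that belong to a confluent cluster
#'
#' Lesions are confluent when connected-components analysis of the lesion
#' support merges voxels of two or more distinct labels into one cluster;
#' every lesion in such a cluster is flagged.
#'
#' @param labels Lesion label array.
#' @param connectivity 26 (default) or 6.
#' @return Logical vector indexed by lesion id 1..K.
#' @export
flag_confluent <- function(labels, connectivity = 26) {
  K <- max(labels)
  if (K < 1) return(logical(0))
  comp <- connected_components(labels > 0, connectivity)
  idx <- which(labels > 0)
  tab <- tibble::tibble(comp = comp[idx], lab = as.integer(labels[idx]))
  n_labels_per_comp <- tapply(tab$lab, tab$comp, function(x) length(unique(x)))
  confluent_comps <- as.integer(names(n_labels_per_comp)[n_labels_per_comp >= 2])
  out <- logical(K)
  hit <- unique(tab$lab[tab$comp %in% confluent_comps])
  out[hit] <- TRUE
  out
}

#' Transfer PRL status from a manual annotation to labelled lesions
#'
#' A lesion is PRL-positive iff it overlaps the annotation mask by at least
#' one voxel (any-overlap rule); an annotation line straddling two lesions
#' marks both.
#'
#' @param labels Lesion label array.
#' @param annotation Binary annotation mask (same grid).
#' @return Logical vector indexed by lesion id 1..K.
#' @export
assign_prl_status <- function(labels, annotation) {
  stop_if_grid_mismatch(labels, annotation, call_name = "assign_prl_status")
  K <- max(labels)
  if (K < 1) return(logical(0))
  hit <- unique(as.integer(labels[annotation != 0 & labels > 0]))
  out <- logical(K)
  out[hit] <- TRUE
  out
}

#' Label distinct lesion instances from a probability map
#'
#' Full labelling stage, in published order: Dice-optimal threshold
#' selection (or a fixed threshold), binarization, one-voxel box dilation,
#' CSF/GM exclusion of newly added voxels, Hessian-based centre detection,
#' nearest-neighbour label transfer, confluence flagging, and PRL status by
#' any-overlap with the manual annotation.
#'
#' @param prob Probability map.
#' @param gold Gold-standard lesion mask (used only to pick the threshold;
#'   ignored when `threshold` is given).
#' @param csf,gm Binary tissue masks (`NULL` for empty).
#' @param annotation Binary manual PRL annotation mask (`NULL` for empty).
#' @param thresholds Candidate threshold grid for [select_threshold()].
#' @param smooth_sigma_vox Gaussian sigma for centre detection.
#' @param threshold Optional fixed threshold bypassing gold-based selection.
#' @param subject_id Identifier copied into the records.
#' @param connectivity Connectivity for confluence analysis (26 or 6).
#' @return List with `labels` (label array), `records` (tibble: subject_id,
#'   lesion_id, size_vox, is_confluent, is_prl_truth), `threshold`,
#'   `n_lesions` and `n_prl`.
#' @export
label_lesions <- function(prob, gold = NULL, csf = NULL, gm = NULL,
                          annotation = NULL,
                          thresholds = seq(0.05, 0.95, by = 0.05),
                          smooth_sigma_vox = 1, threshold = NULL,
                          subject_id = "S01", connectivity = 26) {
  empty <- function() as_volume(array(0, dim(prob)), voxel_size(prob))
  if (is.null(csf)) csf <- empty()
  if (is.null(gm)) gm <- empty()
  if (is.null(annotation)) annotation <- empty()
  if (is.null(threshold)) {
    if (is.null(gold)) stop("either a gold mask or a fixed threshold is required")
    threshold <- select_threshold(prob, gold, thresholds)
  }
  seg <- binarize(prob, threshold)
  dil <- dilate_one_voxel(seg)
  final_mask <- exclude_tissue(dil, seg, csf, gm)
  centers <- detect_centers(prob, final_mask, smooth_sigma_vox)
  labels <- assign_labels_nn(final_mask, centers)
  confl <- flag_confluent(labels, connectivity)
  prl <- assign_prl_status(labels, annotation)
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  records <- tibble::tibble(
    subject_id = subject_id,
    lesion_id = seq_len(max(labels)),
    size_vox = as.integer(sizes),
    is_confluent = confl,
    is_prl_truth = prl)
  list(labels = labels, records = records, threshold = threshold,
       n_lesions = nrow(records), n_prl = sum(records$is_prl_truth))
}
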