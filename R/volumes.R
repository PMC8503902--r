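#' Construct a gridded volume
#'
#' Volumes are plain 3D numeric arrays carrying a `voxel_size_mm` attribute
#' (isometric voxels, so a single scalar describes the grid spacing). All
#' geometry in the package is done in voxel space; with isometric voxels,
#' millimetre and voxel distances differ only by a constant.
#'
#' @param values 3D numeric array.
#' @param voxel_size_mm Positive scalar, edge length of a voxel in mm.
#' @return The array with the `voxel_size_mm` attribute set.
#' @export
as_volume <- function(values, voxel_size_mm = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0) {
    stop("voxel_size_mm must be a positive scalar")
  }
  attr(values, "voxel_size_mm") <- as.numeric(voxel_size_mm)
  values
}

#' Voxel size of a volume
#'
#' @param x A volume created by [as_volume()] or [read_volume()].
#' @return Voxel edge length in mm (1 if the attribute is absent).
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_mm")
  if (is.null(vs)) 1 else vs
}

#' Compare the grids of two volumes
#'
#' Two volumes share a grid when their array dimensions are identical and
#' their voxel sizes agree within 1e-6 mm.
#'
#' @param a,b Gridded volumes.
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b) {
  identical(dim(a), dim(b)) && abs(voxel_size(a) - voxel_size(b)) < 1e-6
}

stop_if_grid_mismatch <- function(..., call_name = "operation") {
  vols <- list(...)
  for (i in seq_along(vols)[-1]) {
    if (!check_same_grid(vols[[1]], vols[[i]])) {
      stop(sprintf("%s: inputs are on different grids", call_name))
    }
  }
  invisible(TRUE)
}

#' Read a 3D NIfTI volume
#'
#' Reads a single-volume NIfTI-1 file and validates it against the
#' requested semantic type. Values are returned untransformed.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param type One of `"auto"` (no value checks), `"phase"` (finite values),
#'   `"probability"` (values in `[0, 1]`) or `"mask"` (values exactly 0/1).
#' @return A 3D array with a `voxel_size_mm` attribute.
#' @details Anisotropic voxel dimensions beyond 1% relative spread trigger a
#'   warning and the mean spacing is used; the pipeline assumes isometric
#'   acquisition.
#' @export
read_volume <- function(path, type = c("auto", "phase", "probability", "mask", "labels")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop(sprintf("%s: expected a 3D single-volume NIfTI", path))
  pd <- RNifti::pixdim(img)[1:3]
  if (any(pd <= 0)) pd[pd <= 0] <- 1
  if ((max(pd) - min(pd)) / mean(pd) > 0.01) {
    warning(sprintf("%s: anisotropic voxels (%.4g, %.4g, %.4g); using mean spacing",
                    path, pd[1], pd[2], pd[3]))
  }
  vals <- array(as.numeric(img), d)
  if (type == "probability" && (min(vals) < 0 || max(vals) > 1)) {
    stop(sprintf("%s: probability map has values outside [0,1]", path))
  }
  if (type == "mask" && !all(vals %in% c(0, 1))) {
    stop(sprintf("%s: mask has values other than 0/1", path))
  }
  if (type == "labels" && (any(vals < 0) || any(vals != round(vals)))) {
    stop(sprintf("%s: label map must hold non-negative integers", path))
  }
  if (type == "phase" && !all(is.finite(vals))) {
    stop(sprintf("%s: phase volume contains non-finite values", path))
  }
  as_volume(vals, mean(pd))
}

#' Write a 3D volume as NIfTI
#'
#' Masks are stored as unsigned 8-bit, label maps as unsigned 16-bit and
#' intensity/probability volumes as 32-bit float.
#'
#' @param vol Volume (3D array, optionally with `voxel_size_mm`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param type `"phase"`, `"probability"`, `"mask"` or `"labels"`; controls
#'   the on-disk datatype.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = c("phase", "probability", "mask", "labels")) {
  type <- match.arg(type)
  dt <- switch(type, mask = "uint8", labels = "uint16", "float")
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- rep(voxel_size(vol), 3)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

## ---- internal array utilities ------------------------------------------

# Shift a 3D array by an integer offset, filling exposed planes with `fill`.
shift_array <- function(a, offset, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- offset[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable 3D Gaussian smoothing with zero padding at the boundary.
gaussian_smooth <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  out <- a
  for (ax in 1:3) {
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- j - r - 1L
      acc <- acc + k[j] * shift_array(out, off)
    }
    out <- acc
  }
  out
}

# Offsets of the 26- or 6-neighbourhood (excluding the origin).
neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# Label connected components of a logical 3D array. Returns an integer array
# (0 background); component ids are arbitrary but deterministic.
connected_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  n <- length(idx)
  if (n == 0L) return(lab)
  pos <- array(0L, d)
  pos[idx] <- seq_len(n)
  offs <- neighbour_offsets(connectivity)
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]  # half-space offsets
  co <- arrayInd(idx, d)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    p <- pos[nb_lin]
    hit <- p > 0L
    if (any(hit)) edges[[i]] <- cbind(which(ok)[hit], p[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Renumber the components of an integer label array so that ids follow the
# lexicographic (i, j, k) order of each component's smallest voxel triple.
renumber_lexicographic <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(lab)
  co <- arrayInd(idx, dim(lab))
  ids <- lab[idx]
  o <- order(co[, 1], co[, 2], co[, 3])
  firsts <- ids[o][!duplicated(ids[o])]  # component ids in lexicographic order
  map <- integer(max(ids))
  map[firsts] <- seq_along(firsts)
  out <- array(0L, dim(lab))
  out[idx] <- map[ids]
  out
}
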