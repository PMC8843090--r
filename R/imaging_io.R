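#' In-memory 4D BOLD series
#'
#' Lightweight container for a 4D BOLD image: the data array (x, y, z, t),
#' the 4x4 voxel-to-world affine (mm) and the repetition time. All
#' downstream spatial math uses world coordinates obtained through the
#' affine, so nothing depends on a particular template space.
#'
#' @param data 4D numeric array, dimensions (x, y, z, t), all finite,
#'   t >= 2.
#' @param affine 4x4 invertible voxel-to-world transform (mm). Voxel
#'   indices are 0-based when mapped through the affine.
#' @param tr_seconds repetition time in seconds, > 0.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine = diag(4), tr_seconds = 1) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop("need at least 2 timepoints")
  if (!all(is.finite(data)))
    stop(sprintf("non-finite voxels: %d", sum(!is.finite(data))))
  check_affine(affine)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be > 0")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_series")
}

#' In-memory 3D scalar density map
#'
#' A 3D scalar image (e.g. a SPECT-like uptake map) with its affine.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "density_map")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("`affine` is not invertible")
  invisible(affine)
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d timepoints, TR = %gs\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map> %d x %d x %d grid\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/-2 image and returns a [bold_series()] (4D) or
#' [density_map()] (3D). No resampling is performed; the stored affine
#' (sform preferred, qform fallback) is returned as-is.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param expect_4d if `TRUE` the file must be 4D (a BOLD series); if
#'   `FALSE` it must be 3D (a scalar map).
#' @param tr_seconds repetition time for 4D images; defaults to the
#'   pixdim(4) stored in the header when positive.
#' @return `bold_series` or `density_map`.
#' @export
load_volume <- function(path, expect_4d = FALSE, tr_seconds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  nd <- length(dim(arr))
  if (expect_4d && nd != 4L)
    stop(sprintf("expected 4D image, got %dD: %s", nd, path))
  if (!expect_4d && nd != 3L)
    stop(sprintf("expected 3D image, got %dD: %s", nd, path))
  if (!all(is.finite(arr)))
    stop(sprintf("non-finite voxels in %s: %d", path, sum(!is.finite(arr))))
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- matrix(as.numeric(aff), 4L, 4L)
  check_affine(aff)
  if (expect_4d) {
    if (is.null(tr_seconds)) {
      pd <- RNifti::pixdim(img)
      tr_seconds <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    }
    bold_series(arr, aff, tr_seconds)
  } else {
    density_map(arr, aff)
  }
}

#' Write a 3D/4D array as NIfTI with a given affine
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"double"` round-trips exactly,
#'   `"float"` is used for mode maps.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, affine, path, datatype = "double") {
  check_affine(affine)
  img <- RNifti::asNifti(data)
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- pd
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Define a region of interest from a (probabilistic) mask volume
#'
#' Thresholds a scalar mask volume and fixes the ROI's voxel ordering:
#' voxels with value strictly greater than `threshold * max(mask)` are
#' included, ordered lexicographically in (i, j, k) voxel indices
#' (0-based, i fastest). This ordering is the single source of truth for
#' every per-voxel product downstream (fingerprints, similarity rows,
#' mode entries, saved maps).
#'
#' @param mask_volume a `density_map` (or 3D array) holding the mask;
#'   probabilistic atlases can be thresholded at e.g. 0.25 of their
#'   maximum, mirroring a 25%-probability atlas cut.
#' @param threshold fraction in \[0, 1\] of the mask maximum; strict
#'   inequality (`value > threshold * max`).
#' @param name label for the ROI.
#' @param affine affine override when `mask_volume` is a bare array.
#' @return An object of class `roi_spec` with fields `name`, `mask`
#'   (logical 3D array), `voxel_index_list` (V x 3 integer matrix of
#'   0-based (i, j, k)), `world_coords` (V x 3, mm) and `affine`.
#' @export
make_roi <- function(mask_volume, threshold = 0.25, name = "roi",
                     affine = NULL) {
  if (inherits(mask_volume, "density_map")) {
    arr <- mask_volume$data
    affine <- mask_volume$affine
  } else {
    arr <- mask_volume
    if (is.null(affine)) affine <- diag(4)
  }
  check_affine(affine)
  if (threshold < 0 || threshold > 1) stop("`threshold` must lie in [0, 1]")
  mx <- max(arr)
  keep <- arr > threshold * mx
  if (!any(keep) || mx <= 0) stop("empty ROI after thresholding")
  idx1 <- which(keep, arr.ind = TRUE)            # 1-based, column-major:
  ord <- order(idx1[, 1], idx1[, 2], idx1[, 3])  # lexicographic, i fastest
  idx1 <- idx1[ord, , drop = FALSE]
  idx0 <- idx1 - 1L
  wc <- t(affine %*% rbind(t(idx0), 1))[, 1:3, drop = FALSE]
  colnames(wc) <- c("x", "y", "z")
  colnames(idx0) <- c("i", "j", "k")
  structure(list(name = name, mask = keep, voxel_index_list = idx0,
                 world_coords = wc, affine = affine),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> '%s': %d voxels\n", x$name, nrow(x$world_coords)))
  invisible(x)
}

#' Number of voxels in an ROI
#' @param roi an `roi_spec`.
#' @return integer voxel count.
#' @export
n_voxels <- function(roi) nrow(roi$voxel_index_list)

#' Extract ROI and reference time-series matrices
#'
#' Builds the two time-by-voxel matrices the mapping operates on: `A`
#' (ROI voxels, columns in `roi` voxel order) and `B` (all brain voxels
#' outside the ROI). Columns are demeaned over time. Zero-variance
#' columns are dropped from `B` (the count is recorded); a zero-variance
#' ROI voxel is an error because every ROI voxel needs a fingerprint.
#'
#' @param bold a [bold_series()].
#' @param roi an `roi_spec` on the same grid.
#' @param brain_mask 3D logical/numeric array marking in-brain voxels;
#'   must contain the ROI.
#' @return A `timeseries_pair`: list with `A` (t x V), `B` (t x W),
#'   `brain_mask`, and `n_dropped` (zero-variance reference columns).
#' @export
extract_timeseries <- function(bold, roi, brain_mask) {
  stopifnot(inherits(bold, "bold_series"), inherits(roi, "roi_spec"))
  d <- dim(bold$data)
  if (!all(d[1:3] == dim(roi$mask)))
    stop("grid mismatch between BOLD image and ROI mask")
  if (!all(d[1:3] == dim(brain_mask)))
    stop("grid mismatch between BOLD image and brain mask")
  brain <- brain_mask > 0
  if (any(roi$mask & !brain))
    stop("brain mask does not contain the ROI")
  t_n <- d[4]
  mat <- matrix(bold$data, prod(d[1:3]), t_n)   # voxels x time
  roi_flat <- roi$voxel_index_list[, 1] + 1L +
    d[1] * roi$voxel_index_list[, 2] +
    d[1] * d[2] * roi$voxel_index_list[, 3]
  A <- t(mat[roi_flat, , drop = FALSE])
  ref_flat <- setdiff(which(brain), roi_flat)
  B <- t(mat[ref_flat, , drop = FALSE])
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  va <- colSums(A^2)
  if (any(va < .Machine$double.eps * t_n))
    stop(sprintf("zero-variance ROI voxel(s): %d",
                 sum(va < .Machine$double.eps * t_n)))
  vb <- colSums(B^2)
  drop <- vb < .Machine$double.eps * t_n
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    message(sprintf("dropping %d zero-variance reference voxel(s)", n_dropped))
    B <- B[, !drop, drop = FALSE]
  }
  structure(list(A = A, B = B, brain_mask = brain, n_dropped = n_dropped),
            class = "timeseries_pair")
}

#' Write a connectivity mode as a NIfTI map
#'
#' Places the mode's per-voxel values at the ROI voxels (0 elsewhere) and
#' writes a 32-bit float NIfTI volume with the ROI's affine.
#'
#' @param mode a `connectivity_mode` (see [laplacian_eigenmaps()]) or a
#'   bare numeric vector of length V.
#' @param roi the `roi_spec` defining the support.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_mode_map <- function(mode, roi, path) {
  vals <- if (inherits(mode, "connectivity_mode")) mode$values else mode
  V <- n_voxels(roi)
  if (length(vals) != V)
    stop(sprintf("mode length %d does not match ROI voxel count %d",
                 length(vals), V))
  vol <- array(0, dim(roi$mask))
  d <- dim(roi$mask)
  flat <- roi$voxel_index_list[, 1] + 1L +
    d[1] * roi$voxel_index_list[, 2] +
    d[1] * d[2] * roi$voxel_index_list[, 3]
  vol[flat] <- vals
  write_volume(vol, roi$affine, path, datatype = "float")
}

#' Extract the within-ROI values of a 3D map in ROI voxel order
#'
#' @param map a `density_map` or 3D array on the ROI grid.
#' @param roi an `roi_spec`.
#' @return numeric vector of length V in `roi` voxel order.
#' @export
roi_values <- function(map, roi) {
  arr <- if (inherits(map, "density_map")) map$data else map
  if (!all(dim(arr) == dim(roi$mask)))
    stop("grid mismatch between map and ROI")
  d <- dim(arr)
  flat <- roi$voxel_index_list[, 1] + 1L +
    d[1] * roi$voxel_index_list[, 2] +
    d[1] * d[2] * roi$voxel_index_list[, 3]
  arr[flat]
}

#' Intensity-normalize a density map within a mask
#'
#' Affinely rescales within-mask values to zero mean and unit variance
#' (outside-mask voxels set to 0). All statistics computed downstream
#' from density maps (Pearson correlations) are invariant to affine
#' rescaling, so this z-scoring dialect is equivalent to any other affine
#' intensity normalization for the analyses in scope.
#'
#' @param map a `density_map`.
#' @param brain_mask 3D logical/numeric array; normalization is computed
#'   over voxels where it is > 0.
#' @return A normalized `density_map`.
#' @export
normalize_density <- function(map, brain_mask) {
  stopifnot(inherits(map, "density_map"))
  msk <- brain_mask > 0
  if (!any(msk)) stop("empty mask")
  v <- map$data[msk]
  s <- sd(v)
  if (!is.finite(s) || s < .Machine$double.eps)
    stop("zero within-mask variance")
  out <- array(0, dim(map$data))
  out[msk] <- (v - mean(v)) / s
  density_map(out, map$affine)
}
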