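#' Brain mask over a 3D voxel grid
#'
#' A logical mask on a 3D grid. Masked voxels are linearized in R's native
#' column-major order, and every matrix in the package indexes voxels in that
#' fixed order, so all I/O paths agree on voxel identity.
#'
#' @param flags Logical 3D array (or vector with a `dim` attribute).
#' @param allow_empty Permit a mask with zero selected voxels. An empty
#'   per-subject mask is representable (two time points can disagree
#'   everywhere); combining masks with [common_mask()] rejects an empty
#'   intersection.
#' @return An object of class `brain_mask` with elements `flags`,
#'   `grid_shape`, `n_voxels`.
#' @export
brain_mask <- function(flags, allow_empty = FALSE) {
  if (is.null(dim(flags)) || length(dim(flags)) != 3L) {
    stop("mask flags must be a 3D logical array")
  }
  flags <- array(as.logical(flags), dim = dim(flags))
  if (anyNA(flags)) stop("mask flags contain NA")
  n <- sum(flags)
  if (n == 0L && !allow_empty) stop("empty mask")
  structure(
    list(flags = flags, grid_shape = dim(flags), n_voxels = n),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("Brain mask: %s grid, %d in-mask voxels\n",
              paste(x$grid_shape, collapse = " x "), x$n_voxels))
  invisible(x)
}

#' Per-subject mask from a 4D volume series
#'
#' For every time point, a voxel is kept iff its value is greater than or
#' equal to the mean over the entire volume at that time point; the subject
#' mask is the element-wise AND of the per-time-point masks. The mean is
#' taken over all array voxels (field-of-view cropping is a preprocessing
#' concern, not handled here).
#'
#' @param volume_series 4D numeric array (x, y, z, time) with at least one
#'   time point.
#' @return A [brain_mask()] (possibly empty; see [common_mask()]).
#' @export
subject_mask <- function(volume_series) {
  d <- dim(volume_series)
  if (is.null(d) || length(d) != 4L || d[4L] < 1L) {
    stop("volume_series must be a 4D array with >= 1 time point")
  }
  assert_finite(volume_series, "volume series")
  if (all(volume_series == 0)) stop("degenerate volume")
  flags <- array(TRUE, dim = d[1:3])
  for (tp in seq_len(d[4L])) {
    vol <- volume_series[, , , tp, drop = FALSE]
    dim(vol) <- d[1:3]
    flags <- flags & (vol >= mean(vol))
  }
  brain_mask(flags, allow_empty = TRUE)
}

#' Group common mask
#'
#' Element-wise AND (the logical analogue of multiplying binary masks) of
#' the per-subject masks, defining the voxels shared by all subjects.
#'
#' @param masks List of [brain_mask()] objects on identical grids.
#' @return A non-empty [brain_mask()].
#' @export
common_mask <- function(masks) {
  if (inherits(masks, "brain_mask")) masks <- list(masks)
  if (length(masks) < 1L) stop("need at least one mask")
  shape <- masks[[1L]]$grid_shape
  flags <- masks[[1L]]$flags
  for (m in masks[-1L]) {
    if (!inherits(m, "brain_mask")) stop("all inputs must be brain_mask objects")
    if (!identical(m$grid_shape, shape)) stop("mask grid shapes differ")
    flags <- flags & m$flags
  }
  if (!any(flags)) stop("empty common mask")
  brain_mask(flags)
}

#' Extract the masked voxels-by-time matrix from a 4D volume
#'
#' @param volume_series 4D numeric array (x, y, z, time).
#' @param mask A [brain_mask()] matching the spatial grid.
#' @return Numeric matrix, `n_voxels` rows by `t` columns, voxels in
#'   column-major grid order.
#' @export
apply_mask <- function(volume_series, mask) {
  d <- dim(volume_series)
  if (is.null(d) || length(d) != 4L) stop("volume_series must be a 4D array")
  if (!identical(d[1:3], as.integer(mask$grid_shape)) &&
      !identical(d[1:3], mask$grid_shape)) {
    stop("volume grid does not match mask grid")
  }
  idx <- which(mask$flags)
  out <- matrix(0, nrow = length(idx), ncol = d[4L])
  for (tp in seq_len(d[4L])) {
    vol <- volume_series[, , , tp, drop = FALSE]
    out[, tp] <- vol[idx]
  }
  out
}

#' Read a 4D NIfTI volume series
#'
#' Thin wrapper over the RNifti reader returning a plain numeric array.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Numeric array (3D or 4D).
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package")
  }
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}
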