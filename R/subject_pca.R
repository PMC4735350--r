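#' Blockwise time-dimension covariance of one subject
#'
#' Accumulates the t x t covariance `t(Z) %*% Z / (v - 1)` over blocks of
#' voxel rows, so only `voxel_block` rows need be resident at a time. The
#' result is independent of the block size (summation is associative) and is
#' the input to the subject-level EVD when the time dimension is small.
#'
#' @param z Column-centered v x t matrix.
#' @param voxel_block Rows per block (default: all rows, a single block).
#' @return Symmetric t x t covariance matrix.
#' @export
subject_cov_blockwise <- function(z, voxel_block = nrow(z)) {
  z <- as.matrix(z)
  check_centered(z, "subject data")
  voxel_block <- as.integer(voxel_block)
  if (voxel_block < 1L) stop("voxel_block must be >= 1")
  v <- nrow(z)
  t_dim <- ncol(z)
  if (t_dim > 10000L) {
    warning("time dimension exceeds 10000; the blockwise t x t path is meant for the small-time regime")
  }
  acc <- matrix(0, t_dim, t_dim)
  start <- 1L
  while (start <= v) {
    end <- min(start + voxel_block - 1L, v)
    blk <- z[start:end, , drop = FALSE]
    acc <- acc + crossprod(blk)
    start <- end + 1L
  }
  acc <- acc / (v - 1)
  (acc + t(acc)) / 2
}

#' First-stage subject PCA reduction
#'
#' Reduces one subject's voxels-by-time matrix to its top `p` principal
#' component score vectors (the `Y_i` fed to the group stage), via EVD of
#' the t x t time covariance. With `whiten = TRUE` each score column is
#' rescaled to unit sample variance (`X = Z F Lambda^{-1/2}` so
#' `t(X) %*% X / (v - 1) = I`); the orthonormal time eigenvectors are
#' returned separately.
#'
#' @param z Column-centered v x t matrix.
#' @param p Number of components to retain (<= min(v, t) and <= rank).
#' @param whiten Rescale scores to unit sample variance (default `TRUE`).
#' @param subject_id Identifier stored on the result.
#' @param voxel_block Optional row-block size for the covariance pass.
#' @return An object of class `reduced_subject`: `scores` (v x p, centered,
#'   `centered` attribute set), `eigenvalues` (p, descending), `loadings`
#'   (t x p orthonormal time eigenvectors), `whitened`, `subject_id`.
#' @export
reduce_subject <- function(z, p, whiten = TRUE,
                           subject_id = attr(z, "subject_id"),
                           voxel_block = nrow(z)) {
  z <- as.matrix(z)
  check_centered(z, "subject data")
  p <- as.integer(p)
  if (p < 1L || p > min(dim(z))) stop("p must be between 1 and min(v, t)")
  cmat <- subject_cov_blockwise(z, voxel_block)
  if (max(abs(cmat)) == 0) stop("zero-variance data")
  e <- sym_eigen(cmat)
  vals <- e$values[seq_len(p)]
  if (vals[p] <= 1e-12 * vals[1L]) {
    stop("p exceeds the numerical rank of the subject data")
  }
  f <- e$vectors[, seq_len(p), drop = FALSE]
  f <- fix_signs(f)
  scores <- z %*% f
  if (whiten) scores <- sweep(scores, 2L, sqrt(vals), `/`)
  attr(scores, "centered") <- TRUE
  attr(scores, "subject_id") <- subject_id
  structure(
    list(scores = scores, eigenvalues = vals, loadings = f,
         whitened = whiten, subject_id = subject_id),
    class = "reduced_subject"
  )
}

#' @export
print.reduced_subject <- function(x, ...) {
  cat(sprintf("Reduced subject %s: %d x %d scores (%s)\n",
              x$subject_id %||% "<unnamed>", nrow(x$scores), ncol(x$scores),
              if (x$whitened) "whitened" else "unwhitened"))
  invisible(x)
}

#' Write / read a reduced subject
#'
#' One self-describing file per subject (R native serialization) holding the
#' scores matrix, eigenvalues, and subject id; readable directly by
#' [group_provider()].
#'
#' @param reduced A `reduced_subject` from [reduce_subject()], or a plain
#'   centered matrix.
#' @param path Output file path.
#' @return `path` invisibly; `read_reduced_subject()` returns the object.
#' @export
write_reduced_subject <- function(reduced, path) {
  saveRDS(reduced, path)
  invisible(path)
}

#' @rdname write_reduced_subject
#' @export
read_reduced_subject <- function(path) readRDS(path)
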