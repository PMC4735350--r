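#' Generate a multi-subject group dataset with planted structure
#'
#' Each subject's v x t matrix is built as
#' `U %*% diag(sqrt(spectrum * (v - 1))) %*% t(A_i) + noise`, where `U` is a
#' shared v x r orthonormal basis with zero-mean columns (so column
#' centering leaves the planted structure intact), `A_i` is a random
#' orthonormal t x r per-subject mixing matrix, and the noise is i.i.d.
#' Gaussian. With `noise_sd = 0` each subject's time covariance has
#' eigenvalues exactly `spectrum`, and the group voxel covariance equals
#' `M * U diag(spectrum) t(U)`, so the planted group spectrum is
#' `M * spectrum`.
#'
#' When `smoothness > 0` the basis columns are generated on a synthetic 3D
#' voxel grid and smoothed with a separable kernel of that width before
#' re-orthonormalization, giving the spatial regularity that voxel
#' subsampling (SVP) relies on in real smoothed data.
#'
#' @param v Number of voxels (rows).
#' @param t Number of time points per subject.
#' @param M Number of subjects.
#' @param r Planted rank (<= min(v, t)).
#' @param spectrum Positive descending vector of length `r`; default a
#'   geometric decay `10 * 0.85^(0:(r-1))`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param smoothness Width (in voxels) of the 3D smoothing kernel applied to
#'   the planted basis; 0 disables smoothing.
#' @param seed Integer seed; the output is deterministic per seed.
#' @return List with `subjects` (list of M centered v x t matrices) and
#'   `truth`, an object of class `synthetic_ground_truth` holding
#'   `planted_basis`, `planted_spectrum`, `group_spectrum` (= M * spectrum),
#'   `noise_sd`, `smoothness`, `seed`, `subject_mixing`, and (if smoothed)
#'   `grid_shape`.
#' @export
generate_group <- function(v, t, M, r,
                           spectrum = 10 * 0.85^(seq_len(r) - 1),
                           noise_sd = 0.1, smoothness = 0, seed = 0) {
  v <- as.integer(v); t <- as.integer(t); M <- as.integer(M); r <- as.integer(r)
  if (r > min(v, t)) stop("planted rank r must be <= min(v, t)")
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != r) stop("spectrum must have length r")
  if (any(spectrum <= 0) || any(diff(spectrum) > 0)) {
    stop("spectrum must be positive and descending")
  }
  set.seed(seed)
  g <- matrix(stats::rnorm(v * r), v, r)
  grid_shape <- NULL
  if (smoothness > 0) {
    grid_shape <- fit_grid(v)
    g <- apply(g, 2L, smooth_grid_column, grid_shape = grid_shape,
               width = smoothness, v = v)
  }
  g <- sweep(g, 2L, colMeans(g), `-`)          # zero-mean columns survive centering
  u <- qr.Q(qr(g))
  u <- sweep(u, 2L, colMeans(u), `-`)          # re-center (QR can reintroduce tiny means)
  u <- qr.Q(qr(u))
  scale <- sqrt(spectrum * (v - 1))
  subjects <- vector("list", M)
  mixing <- vector("list", M)
  for (i in seq_len(M)) {
    a <- qr.Q(qr(matrix(stats::rnorm(t * r), t, r)))
    mixing[[i]] <- a
    z <- u %*% (scale * t(a))
    if (noise_sd > 0) z <- z + noise_sd * matrix(stats::rnorm(v * t), v, t)
    subjects[[i]] <- center_columns(z, subject_id = paste0("sim", i))
  }
  truth <- structure(
    list(planted_basis = u, planted_spectrum = spectrum,
         group_spectrum = M * spectrum, noise_sd = noise_sd,
         smoothness = smoothness, seed = seed, subject_mixing = mixing,
         grid_shape = grid_shape),
    class = "synthetic_ground_truth"
  )
  list(subjects = subjects, truth = truth)
}

#' @noRd
#' Near-cubic 3D grid with at least v cells.
fit_grid <- function(v) {
  side <- ceiling(v^(1 / 3))
  dims <- c(side, side, side)
  while (prod(dims) < v) dims[1L] <- dims[1L] + 1L
  as.integer(dims)
}

#' @noRd
#' Separable moving-average smoothing of one basis column on a 3D grid.
smooth_grid_column <- function(col, grid_shape, width, v) {
  full <- numeric(prod(grid_shape))
  full[seq_len(v)] <- col
  arr <- array(full, dim = grid_shape)
  w <- max(1L, as.integer(round(width)))
  kern <- rep(1 / (2 * w + 1), 2 * w + 1)
  smooth1d <- function(x) {
    n <- length(x)
    padded <- c(rep(x[1L], w), x, rep(x[n], w))
    as.numeric(stats::filter(padded, kern, sides = 2))[(w + 1L):(w + n)]
  }
  for (j in seq_len(grid_shape[2L])) for (l in seq_len(grid_shape[3L])) {
    arr[, j, l] <- smooth1d(arr[, j, l])
  }
  for (i in seq_len(grid_shape[1L])) for (l in seq_len(grid_shape[3L])) {
    arr[i, , l] <- smooth1d(arr[i, , l])
  }
  for (i in seq_len(grid_shape[1L])) for (j in seq_len(grid_shape[2L])) {
    arr[i, j, ] <- smooth1d(arr[i, j, ])
  }
  as.numeric(arr)[seq_len(v)]
}

#' Ready-made validation fixtures
#'
#' Builds a group dataset at one of three desk-scale sizes, runs the
#' first-stage subject PCA on every synthetic subject (exercising the same
#' two-stage pipeline used on real data), and wraps the reduced subjects in
#' a [group_provider()]. Profiles: `tiny` (v=500, t=30, M=4, p=10, r=6),
#' `small` (v=3000, t=50, M=10, p=20, r=15), `medium` (v=8000, t=60, M=40,
#' p=30, r=20); all use the geometric planted spectrum, `noise_sd = 0.1`,
#' a 2-voxel spatial smoothing of the planted basis on a synthetic 3D grid
#' (voxel subsampling needs spatially regular data, as on real smoothed
#' volumes), and seed 0 by default. The subject stage keeps unwhitened
#' scores so the planted group spectrum (and its eigengaps) survives to the
#' group stage; pass `whiten = TRUE` for the variance-normalized variant.
#'
#' @param profile `"tiny"`, `"small"`, or `"medium"`.
#' @param mode Provider mode, `"stacked"` or `"unstacked"`.
#' @param seed Integer seed (default 0).
#' @param whiten Whiten the subject-level scores (default `FALSE`).
#' @return List with `provider`, `truth`, `subjects` (the raw v x t
#'   matrices), `reduced` (per-subject [reduce_subject()] results), `mask`
#'   (full-grid [brain_mask()] matching the fixture's voxel ordering),
#'   `scheme` (spatial depth-2 [build_scheme()]), and the profile
#'   parameters `v`, `t`, `M`, `p`, `r`.
#' @export
default_fixture <- function(profile = c("tiny", "small", "medium"),
                            mode = c("stacked", "unstacked"),
                            seed = 0, whiten = FALSE) {
  profile <- match.arg(profile)
  mode <- match.arg(mode)
  par <- switch(profile,
    tiny   = list(v = 500L,  t = 30L, M = 4L,  p = 10L, r = 6L),
    small  = list(v = 3000L, t = 50L, M = 10L, p = 20L, r = 15L),
    medium = list(v = 8000L, t = 60L, M = 40L, p = 30L, r = 20L)
  )
  gen <- generate_group(par$v, par$t, par$M, par$r, noise_sd = 0.1,
                        smoothness = 2, seed = seed)
  reduced <- lapply(gen$subjects, reduce_subject, p = par$p, whiten = whiten)
  provider <- group_provider(lapply(reduced, `[[`, "scores"), mode = mode,
                             subject_ids = paste0("sim", seq_len(par$M)))
  flags <- array(FALSE, dim = gen$truth$grid_shape)
  flags[seq_len(par$v)] <- TRUE
  mask <- brain_mask(flags)
  scheme <- build_scheme(mask, depth = 2L)
  c(list(provider = provider, truth = gen$truth, subjects = gen$subjects,
         reduced = reduced, mask = mask, scheme = scheme), par)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: rank %d, noise sd %.3g, seed %d\n",
              length(x$planted_spectrum), x$noise_sd, x$seed))
  invisible(x)
}
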