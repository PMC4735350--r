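#' Voxel subsampling scheme for SVP
#'
#' Splits the masked voxels into two disjoint index sets by lattice parity.
#' On a 3D grid with depth 2, the "odd" set holds masked voxels whose
#' 1-based grid coordinates are all odd and the "even" set those with all
#' coordinates even, each roughly v/8 of a full grid. For non-spatial data
#' (no mask), strided index sets with offsets 0 and depth - 1 are used.
#'
#' @param mask A [brain_mask()], or an integer `v` for non-spatial data.
#' @param depth Subsampling depth per axis (>= 2; depth 1 would make
#'   disjoint sets impossible).
#' @return Object of class `subsample_scheme`: `depth`, `odd_index_set`,
#'   `even_index_set` (indices into the masked voxel ordering).
#' @export
build_scheme <- function(mask, depth = 2L) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("no subsampling: depth must be >= 2")
  if (inherits(mask, "brain_mask")) {
    idx <- which(mask$flags, arr.ind = TRUE)   # masked voxels, column-major order
    all_odd <- rowSums(idx %% depth == 1L) == 3L
    all_even <- rowSums(idx %% depth == 0L) == 3L
    odd_set <- which(all_odd)
    even_set <- which(all_even)
  } else {
    v <- as.integer(mask)
    if (v < 2L) stop("need at least 2 voxels")
    pos <- seq_len(v)
    odd_set <- pos[(pos - 1L) %% depth == 0L]
    even_set <- pos[(pos - 1L) %% depth == depth - 1L]
  }
  if (length(odd_set) == 0L || length(even_set) == 0L) {
    stop("a subsample index set is empty; mask too sparse for this depth")
  }
  structure(
    list(depth = depth, odd_index_set = odd_set, even_index_set = even_set),
    class = "subsample_scheme"
  )
}

#' @export
print.subsample_scheme <- function(x, ...) {
  cat(sprintf("Subsample scheme: depth %d, |odd| = %d, |even| = %d\n",
              x$depth, length(x$odd_index_set), length(x$even_index_set)))
  invisible(x)
}

#' @noRd
#' Top-c eigenpairs of the subsampled voxel covariances for both parity sets,
#' accumulated in a single pass over the subjects.
subsampled_voxel_bases <- function(provider, rows_a, rows_b, c) {
  acc_a <- matrix(0, length(rows_a), length(rows_a))
  acc_b <- matrix(0, length(rows_b), length(rows_b))
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    acc_a <- acc_a + tcrossprod(yi[rows_a, , drop = FALSE])
    acc_b <- acc_b + tcrossprod(yi[rows_b, , drop = FALSE])
  }
  top <- function(acc) {
    e <- sym_eigen(acc / (provider$v - 1))
    keep <- seq_len(min(c, sum(e$values > 1e-12 * max(e$values, 1e-300))))
    list(basis = e$vectors[, keep, drop = FALSE], values = e$values[keep])
  }
  list(a = top(acc_a), b = top(acc_b))
}

#' Subsampled voxel PCA (SVP)
#'
#' Fast approximate group PCA: EVD is run in the reduced voxel space of
#' each parity set (so `v' < Mp` and the voxel-dimension covariance sum is
#' cheap), the resulting bases are projected back to full voxel dimension
#' through the data, and a joint 2k' x 2k' Gram step merges the two
#' half-space estimates. The subspace costs two dataloads per subject in
#' unstacked mode; reading out data-scale eigenvalues and the
#' back-projection matrix takes one further pass (the merge-Gram spectrum
#' lives on the squared data scale and is not comparable to the exact EVD
#' spectrum). The result is approximate and is intended as a warm start for
#' [mpowit()] or [large_pca()], or as a quick standalone estimate.
#'
#' @param provider A [group_provider()].
#' @param k Number of components returned.
#' @param k_intermediate Intermediate model order k' estimated in each
#'   subsampled space; default `min(500, v', Mp)` (500 is the recommended
#'   order when k is around 100).
#' @param scheme A [build_scheme()]; default strided scheme of depth 2 over
#'   the provider's rows.
#' @return A [pca_result()] with method `"svp"`; eigenvalues are the
#'   Rayleigh-Ritz values of the group covariance on the recovered
#'   subspace, hence never above the exact ones.
#' @export
svp <- function(provider, k, k_intermediate = NULL, scheme = NULL) {
  stopifnot(inherits(provider, "group_provider"))
  k <- as.integer(k)
  scheme <- scheme %||% build_scheme(provider$v)
  rows_a <- scheme$odd_index_set
  rows_b <- scheme$even_index_set
  mp <- provider$M * provider$p
  vmin <- min(length(rows_a), length(rows_b))
  kint <- as.integer(k_intermediate %||% min(500L, vmin, mp))
  if (kint > mp) stop("k_intermediate exceeds Mp")
  if (kint > vmin) stop("k_intermediate exceeds the subsampled voxel dimension")
  if (k > kint) stop("k must be <= k_intermediate")
  loads0 <- dataloads(provider)
  v <- provider$v

  # pass 1: EVD in each subsampled voxel space (both parities, one pass)
  bases <- subsampled_voxel_bases(provider, rows_a, rows_b, kint)
  ea <- bases$a
  eb <- bases$b

  # pass 2: project subsampled bases through the data back to full dimension:
  # F_a = t(t(X_a) %*% Y_a), X_a_full = Y %*% F_a (one joint pass)
  xa <- matrix(0, v, ncol(ea$basis))
  xb <- matrix(0, v, ncol(eb$basis))
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    xa <- xa + yi %*% crossprod(yi[rows_a, , drop = FALSE], ea$basis)
    xb <- xb + yi %*% crossprod(yi[rows_b, , drop = FALSE], eb$basis)
  }

  # joint 2k' x 2k' Gram merge; eigenvectors give the merged orthonormal basis
  xab <- cbind(xa, xb)
  gram <- crossprod(xab) / (v - 1)
  e <- sym_eigen(gram)
  good <- e$values > 1e-10 * max(e$values, 1e-300)
  if (sum(good) < k) stop("rank collapse in the joint Gram matrix")
  w <- e$vectors[, seq_len(k), drop = FALSE]
  basis <- xab %*% w %*% diag(1 / sqrt((v - 1) * e$values[seq_len(k)]), k)

  # pass 3: Rayleigh-Ritz eigenvalues and back-projection on the subspace
  chi <- matrix(0, v, k)
  f <- matrix(0, mp, k)
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    fi <- crossprod(yi, basis)
    rows <- ((i - 1L) * provider$p + 1L):(i * provider$p)
    f[rows, ] <- fi
    chi <- chi + yi %*% fi
  }
  small <- crossprod(basis, chi) / (v - 1)
  er <- sym_eigen(small)
  vals <- er$values
  basis <- basis %*% er$vectors
  f <- f %*% er$vectors
  pca_result(basis, vals, backproj = f, method = "svp", v = v,
             dataloads = list(subspace = 2L * provider$M,
                              total = dataloads(provider) - loads0))
}

#' Subsampled time PCA (STP)
#'
#' Single-pass approximate group PCA: subjects are consumed in groups of
#' `g`, each group's gp x gp time covariance is eigendecomposed, the group
#' subspace `X_g = Y_g F_g` (variance-weighted, not whitened) is merged
#' into the running estimate through a 2k' x 2k' Gram step, and the merged
#' estimate is truncated back to k' columns so memory stays bounded. Only
#' the final estimate is rescaled (`X = X_g Lambda^{-1/2}`). Because every
#' projection applied to the data is orthonormal, the merge-Gram
#' eigenvalues are genuine Rayleigh-Ritz values of the group covariance, so
#' no extra read-out pass is needed: STP makes exactly one pass (M
#' dataloads). With `g = 1` this is MELODIC's incremental group PCA (MIGP)
#' as a special case; with `g >= M` it reduces to exact EVD truncated to k.
#'
#' @param provider A [group_provider()].
#' @param k Number of components returned.
#' @param k_intermediate Intermediate model order k' kept between merges;
#'   default `min(500, Mp)`. If the first group has `g * p < k'`, k' is
#'   lowered to `g * p` with a warning.
#' @param g Subjects per group (default 20).
#' @param shuffle Optionally permute subject order before grouping.
#' @param seed Seed for the permutation when `shuffle = TRUE`.
#' @param compute_backproj Also read out the back-projection matrix `F`
#'   (costs one extra pass, breaking the single-pass contract; default
#'   `FALSE`).
#' @return A [pca_result()] with method `"stp"`.
#' @export
stp <- function(provider, k, k_intermediate = NULL, g = 20L,
                shuffle = FALSE, seed = 0, compute_backproj = FALSE) {
  stopifnot(inherits(provider, "group_provider"))
  k <- as.integer(k)
  g <- max(1L, as.integer(g))
  p <- provider$p
  M <- provider$M
  v <- provider$v
  mp <- M * p
  kint <- as.integer(k_intermediate %||% min(500L, mp))
  if (k > kint) stop("k must be <= k_intermediate")
  if (min(g, M) * p < kint) {
    warning(sprintf("first group has g*p = %d < k_intermediate = %d; lowering k_intermediate to %d",
                    min(g, M) * p, kint, min(g, M) * p))
    kint <- min(g, M) * p
    if (k > kint) stop("k exceeds the lowered k_intermediate")
  }
  order_idx <- seq_len(M)
  if (shuffle) {
    set.seed(seed)
    order_idx <- sample(order_idx)
  }
  groups <- split(order_idx, ceiling(seq_along(order_idx) / g))
  loads0 <- dataloads(provider)

  x_run <- NULL
  vals_run <- NULL
  for (grp in groups) {
    yg <- do.call(cbind, lapply(grp, function(i) subject_matrix(provider, i)))
    cg <- crossprod(yg) / (v - 1)
    e <- sym_eigen(cg)
    keep <- seq_len(min(kint, ncol(yg),
                        sum(e$values > 1e-12 * max(e$values, 1e-300))))
    fg <- e$vectors[, keep, drop = FALSE]
    xg <- yg %*% fg                                    # variance-weighted
    if (is.null(x_run)) {
      x_run <- xg
      vals_run <- e$values[keep]
    } else {
      xab <- cbind(x_run, xg)
      gram <- crossprod(xab) / (v - 1)
      em <- sym_eigen(gram)
      keep2 <- seq_len(min(kint, sum(em$values > 1e-12 * max(em$values, 1e-300))))
      w <- em$vectors[, keep2, drop = FALSE]
      x_run <- xab %*% w
      vals_run <- em$values[keep2]
    }
  }
  pass_loads <- dataloads(provider) - loads0
  if (length(vals_run) < k) stop("rank collapse: fewer than k components recovered")
  vals <- vals_run[seq_len(k)]
  whit <- x_run[, seq_len(k), drop = FALSE] %*% diag(1 / sqrt(vals), k)
  basis <- whit / sqrt(v - 1)
  f <- if (compute_backproj) make_backproj(provider, basis) else NULL
  pca_result(basis, vals, backproj = f, method = "stp", v = v,
             dataloads = list(pass = pass_loads,
                              total = dataloads(provider) - loads0))
}
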