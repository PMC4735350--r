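#' Cross-covariance of the stacked time dimension
#'
#' The (Mp) x (Mp) group covariance `C = t(Y) %*% Y / (v - 1)`, assembled
#' block-by-block from subject pairs `C_ij = t(Y_i) %*% Y_j / (v - 1)` so
#' that at most two subject matrices are in memory at a time in unstacked
#' mode. Off-diagonal blocks are computed once (`M (M - 1) / 2` block
#' products) and mirrored.
#'
#' @param provider A [group_provider()].
#' @param cap Refuse to build a covariance larger than `cap` on a side
#'   (default 20000); an iterative solver ([mpowit()], [large_pca()]) should
#'   be used instead above it.
#' @return Symmetric (Mp) x (Mp) matrix.
#' @export
cross_cov_time <- function(provider, cap = 20000L) {
  stopifnot(inherits(provider, "group_provider"))
  mp <- provider$M * provider$p
  if (mp > cap) {
    stop(sprintf("Mp = %d exceeds the covariance cap (%d); use an iterative solver such as mpowit() or large_pca()",
                 mp, cap))
  }
  p <- provider$p
  denom <- provider$v - 1
  cmat <- matrix(0, mp, mp)
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    ri <- ((i - 1L) * p + 1L):(i * p)
    cmat[ri, ri] <- crossprod(yi) / denom
    if (i < provider$M) {
      for (j in seq(i + 1L, provider$M)) {
        yj <- subject_matrix(provider, j)
        rj <- ((j - 1L) * p + 1L):(j * p)
        blk <- crossprod(yi, yj) / denom
        cmat[ri, rj] <- blk
        cmat[rj, ri] <- t(blk)
      }
    }
  }
  (cmat + t(cmat)) / 2
}

#' Voxel-dimension covariance as a sum over subjects
#'
#' `C^v = sum_i Y_i %*% t(Y_i) / (v - 1)`, accumulated one subject at a
#' time (exactly M dataloads). Shares its nonzero eigenvalues with the
#' time-dimension covariance of [cross_cov_time()].
#'
#' @inheritParams cross_cov_time
#' @return Symmetric v x v matrix.
#' @export
voxel_cov_sum <- function(provider, cap = 20000L) {
  stopifnot(inherits(provider, "group_provider"))
  v <- provider$v
  if (v > cap) {
    stop(sprintf("v = %d exceeds the covariance cap (%d); use an iterative solver such as mpowit() or large_pca()",
                 v, cap))
  }
  acc <- matrix(0, v, v)
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    acc <- acc + tcrossprod(yi)
  }
  acc <- acc / (v - 1)
  (acc + t(acc)) / 2
}

#' Exact group PCA by eigenvalue decomposition
#'
#' Reference solver and accuracy oracle for the iterative methods. The
#' covariance is formed in the smaller dimension of the stacked data: the
#' (Mp) x (Mp) time path when `Mp < v` (basis obtained by projecting the top
#' eigenvectors onto the data, `X = Y F Lambda^{-1/2}`), otherwise the v x v
#' voxel path (basis directly from the eigenvectors of `C^v`, whitened as
#' `chi * sqrt(v - 1)`).
#'
#' @param provider A [group_provider()].
#' @param k Number of group components (<= rank of Y).
#' @param cap Covariance dimension cap, see [cross_cov_time()].
#' @param path `"auto"` (smaller dimension), `"time"`, or `"voxel"`.
#' @return A [pca_result()].
#' @export
evd_group_pca <- function(provider, k, cap = 20000L,
                          path = c("auto", "time", "voxel")) {
  stopifnot(inherits(provider, "group_provider"))
  path <- match.arg(path)
  mp <- provider$M * provider$p
  v <- provider$v
  k <- as.integer(k)
  if (k < 1L || k > min(v, mp)) stop("k must be between 1 and min(v, Mp)")
  if (path == "auto") {
    if (mp <= cap && mp < v) path <- "time"
    else if (v <= cap) path <- "voxel"
    else if (mp <= cap) path <- "time"
    else stop("both data dimensions exceed the covariance cap; use mpowit() or large_pca()")
  }
  loads0 <- dataloads(provider)
  if (path == "time") {
    cmat <- cross_cov_time(provider, cap = cap)
    e <- sym_eigen(cmat)
    vals <- e$values[seq_len(k)]
    if (vals[k] <= 1e-12 * max(vals[1L], 1e-300)) {
      stop("k exceeds the numerical rank of the group data")
    }
    f <- e$vectors[, seq_len(k), drop = FALSE]
    whit <- expand_time(provider, f) %*% diag(1 / sqrt(vals), k)
    basis <- whit / sqrt(v - 1)
    res <- pca_result(basis, vals, backproj = f, method = "evd",
                      v = v, dataloads = list(total = dataloads(provider) - loads0))
  } else {
    cmat <- voxel_cov_sum(provider, cap = cap)
    e <- sym_eigen(cmat)
    vals <- e$values[seq_len(k)]
    if (vals[k] <= 1e-12 * max(vals[1L], 1e-300)) {
      stop("k exceeds the numerical rank of the group data")
    }
    basis <- e$vectors[, seq_len(k), drop = FALSE]
    f <- make_backproj(provider, basis)
    res <- pca_result(basis, vals, backproj = f, method = "evd",
                      v = v, dataloads = list(total = dataloads(provider) - loads0))
  }
  res
}
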