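# Internal numerical helpers shared by the solvers.

#' Principal angles between two subspaces
#'
#' Canonical (principal) angles between the column spaces of `a` and `b`,
#' in radians, computed from the singular values of the product of their
#' orthonormal bases. Zero angles mean the subspaces coincide.
#'
#' @param a,b Numeric matrices with the same number of rows; their column
#'   spaces are compared (columns need not be orthonormal).
#' @return Numeric vector of `min(ncol(a), ncol(b))` angles in radians,
#'   ascending.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  cmat <- crossprod(qa, qb)
  cosv <- svd(cmat, nu = 0, nv = 0)$d            # descending cosines
  theta <- acos(pmin(pmax(cosv, -1), 1))          # ascending angles
  # acos loses accuracy near 0 (floor ~ sqrt(eps)); refine small angles with
  # the sine-based residual formula, accurate down to machine precision
  if (ncol(qa) == ncol(qb)) {
    sinv <- sort(svd(qb - qa %*% cmat, nu = 0, nv = 0)$d)  # ascending sines
    small <- cosv^2 > 0.5
    theta[small] <- asin(pmin(pmax(sinv[small], 0), 1))
  }
  sort(theta)
}

l2norm <- function(x) sqrt(sum(x^2))

#' @noRd
#' Fix eigenvector signs: largest-magnitude entry of each column positive.
fix_signs <- function(m) {
  if (is.null(dim(m))) m <- as.matrix(m)
  sgn <- apply(m, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  sweep(m, 2L, sgn, `*`)
}

#' @noRd
#' Symmetric EVD with descending eigenvalues, tiny negatives clipped to 0.
sym_eigen <- function(m, clip = TRUE) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (clip) e$values[e$values < 0 & e$values > -1e-10 * max(abs(e$values), 1)] <- 0
  e
}

assert_finite <- function(x, what = "matrix") {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains NaN or Inf entries", what), call. = FALSE)
  }
  invisible(x)
}

is_col_centered <- function(m, tol = 1e-8) {
  scale <- max(abs(m), 1e-300)
  max(abs(colMeans(m))) <= tol * scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x
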