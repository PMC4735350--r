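#' Fast EVD-based orthonormalization
#'
#' Returns an orthonormal basis for the column space of `m` via the full
#' EVD of the small Gram matrix `t(m) %*% m = F D t(F)`: the result is
#' `m %*% F %*% L^{-1}` with `L` the diagonal of column L2-norms of
#' `m %*% F`. Numerically dependent columns (Gram eigenvalue below
#' `1e-12` of the largest) are dropped with a warning. For tall thin `m`
#' this is typically faster than an economy QR and is the
#' orthonormalization used inside [mpowit()].
#'
#' @param m Numeric v x c matrix, `c <= v`.
#' @return Matrix with orthonormal columns spanning `range(m)` (possibly
#'   fewer than `c` if rank deficient).
#' @export
orth_evd <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) > nrow(m)) stop("orth_evd expects c <= v (tall matrix)")
  gram <- crossprod(m)
  e <- eigen((gram + t(gram)) / 2, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values, 1e-300)
  if (!all(keep)) {
    warning(sprintf("dropping %d numerically dependent column(s) in orth_evd",
                    sum(!keep)))
  }
  f <- e$vectors[, keep, drop = FALSE]
  mf <- m %*% f
  l <- sqrt(colSums(mf^2))
  sweep(mf, 2L, l, `/`)
}

#' Classic power iteration for the dominant eigenpair
#'
#' Single-vector power iteration on a symmetric PSD operator: iterate
#' `x <- C x`, renormalize to unit L2 norm, stop when the direction change
#' drops below `tol`; the eigenvalue is the Rayleigh quotient. Included as
#' the reference one-component special case of subspace iteration;
#' estimating many components this way (deflation) accumulates error and is
#' not provided.
#'
#' @param cov_apply Function taking and returning a length-v vector,
#'   applying the covariance operator.
#' @param v Dimension of the operator.
#' @param tol Direction-change tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 1000).
#' @param seed Seed for the Gaussian start vector.
#' @return List with `vector` (unit-norm dominant eigenvector),
#'   `value` (Rayleigh quotient), `iterations`.
#' @export
power_iteration <- function(cov_apply, v, tol = 1e-6, max_iter = 1000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(v)
  x <- x / l2norm(x)
  for (j in seq_len(max_iter)) {
    cx <- cov_apply(x)
    nrm <- l2norm(cx)
    if (nrm == 0) stop("covariance operator annihilated the iterate")
    xnew <- cx / nrm
    # sign-insensitive direction change
    delta <- min(l2norm(xnew - x), l2norm(xnew + x))
    x <- xnew
    if (delta < tol) {
      return(list(vector = x, value = sum(x * cov_apply(x)),
                  iterations = j))
    }
  }
  err <- structure(
    class = c("grouppca_nonconvergence", "error", "condition"),
    list(message = sprintf("power iteration did not converge in %d iterations (spectral gap too small?)",
                           max_iter),
         call = sys.call(-1), last_iterate = x))
  stop(err)
}

#' Multi power iteration (MPOWIT) group PCA
#'
#' Subspace iteration on an enlarged projecting subspace of dimension
#' `l * k`: because the leading components of a power iteration converge
#' much faster than the trailing ones, monitoring only the top k
#' eigenvalues of an l-times-larger subspace cuts the iteration count (and
#' with it the number of dataloads) substantially without losing accuracy.
#' Each iteration orthonormalizes the previous projection with [orth_evd()],
#' applies the group covariance through one pass over the subjects
#' (exactly M dataloads in unstacked mode, `(j + 1) * M` in total), takes
#' the full EVD of the small `(lk) x (lk)` projected matrix
#' `t(X_j) %*% chi_j / (v - 1)`, and stops when the L2 norm of the change
#' in the top-k eigenvalues falls below `tol`. Starting from `Lambda_0 = 0`
#' guarantees at least two iterations under random initialization.
#'
#' With a warm start (an SVP or STP [pca_result()]), `X_0` is the top
#' `l * k` warm components and `Lambda_0` their eigenvalues; convergence
#' then typically needs only 2-3 iterations.
#'
#' @param provider A [group_provider()].
#' @param k Number of components.
#' @param l Integer subspace multiplier (default 5). `l * k` should stay
#'   at or below 500 to keep the small EVD cheap; if `l * k` exceeds
#'   `min(v, Mp)`, `l` is reduced with a warning.
#' @param tol Eigenvalue convergence tolerance (default 1e-6);
#'   `relative = TRUE` divides by the current eigenvalue norm.
#' @param max_iter Maximum iterations (default 1000).
#' @param init `NULL` (Gaussian random `X_0`), or a [pca_result()] /
#'   matrix warm start.
#' @param seed Seed for the Gaussian initialization.
#' @param relative Use a relative convergence norm (default absolute).
#' @param scaling `"unit_variance"` (default: whitened columns have unit
#'   sample variance) or `"eigs"` (verbatim `X_j W_j Lambda_j^{-1/2}`
#'   column scaling for compatibility; the orthonormal basis is identical
#'   either way).
#' @param orth Orthonormalization backend: `"evd"` (the fast [orth_evd()]
#'   route, default) or `"qr"` (economy QR). The fixed point, and hence the
#'   returned eigenvalues, do not depend on this choice.
#' @return A [pca_result()] with method `"mpowit"`; `trace` holds the
#'   per-iteration top-k eigenvalue vectors and difference norms.
#' @export
mpowit <- function(provider, k, l = 5L, tol = 1e-6, max_iter = 1000L,
                   init = NULL, seed = NULL, relative = FALSE,
                   scaling = c("unit_variance", "eigs"),
                   orth = c("evd", "qr")) {
  stopifnot(inherits(provider, "group_provider"))
  scaling <- match.arg(scaling)
  orth <- match.arg(orth)
  orth_fun <- if (orth == "evd") orth_evd else function(m) qr.Q(qr(m))
  k <- as.integer(k)
  l <- as.integer(l)
  if (l < 1L) stop("l must be a positive integer")
  if (tol <= 0) stop("tol must be positive")
  v <- provider$v
  mp <- provider$M * provider$p
  rank_cap <- min(v, mp)
  if (l * k > rank_cap) {
    l_new <- max(1L, rank_cap %/% k)
    warning(sprintf("l*k = %d exceeds min(v, Mp) = %d; reducing l to %d",
                    l * k, rank_cap, l_new))
    l <- l_new
  }
  lk <- l * k
  if (k > lk) stop("k exceeds the projecting subspace size")
  loads0 <- dataloads(provider)

  if (is.null(init)) {
    if (!is.null(seed)) set.seed(seed)
    x0 <- matrix(stats::rnorm(v * lk), v, lk)
    lambda_prev <- rep(0, k)
  } else {
    warm_basis <- if (inherits(init, "pca_result")) init$basis else as.matrix(init)
    warm_vals <- if (inherits(init, "pca_result")) init$eigenvalues else NULL
    if (nrow(warm_basis) != v) stop("warm-start basis has wrong row count")
    take <- min(lk, ncol(warm_basis))
    if (take < lk) {
      if (!is.null(seed)) set.seed(seed)
      pad <- matrix(stats::rnorm(v * (lk - take)), v, lk - take)
      x0 <- cbind(warm_basis[, seq_len(take), drop = FALSE], pad)
    } else {
      x0 <- warm_basis[, seq_len(lk), drop = FALSE]
    }
    lambda_prev <- if (!is.null(warm_vals) && length(warm_vals) >= k) {
      warm_vals[seq_len(k)]
    } else rep(0, k)
  }

  chi <- cov_apply(provider, x0)           # initial power application
  eig_history <- list()
  diff_norms <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  xj <- NULL
  wj <- NULL
  lambda_lk <- NULL
  proj <- NULL
  for (j in seq_len(max_iter)) {
    xj <- orth_fun(chi)
    # one pass: chi = (Y Y^T) X_j and, from the same subject products,
    # proj = t(Y) X_j (reused at convergence for F without an extra pass)
    step <- cov_apply_tracked(provider, xj)
    proj <- step$proj
    chi <- step$chi
    small <- crossprod(xj, chi) / (v - 1)
    e <- sym_eigen(small)
    lambda_lk <- e$values
    wj <- e$vectors
    lambda_j <- lambda_lk[seq_len(k)]
    eig_history[[j]] <- lambda_j
    d <- l2norm(lambda_j - lambda_prev)
    if (relative) d <- d / max(l2norm(lambda_j), 1e-300)
    diff_norms <- c(diff_norms, d)
    iterations <- j
    if (d < tol) { converged <- TRUE; break }
    lambda_prev <- lambda_j
  }
  trace <- list(eigenvalue_history = eig_history, diff_norms = diff_norms,
                converged = converged, iterations = iterations)
  if (!converged) {
    err <- structure(
      class = c("grouppca_nonconvergence", "error", "condition"),
      list(message = sprintf("mpowit did not converge in %d iterations", max_iter),
           call = sys.call(-1), trace = trace))
    stop(err)
  }
  loads_iter <- dataloads(provider) - loads0
  vals <- lambda_lk[seq_len(k)]
  wk <- wj[, seq_len(k), drop = FALSE]
  basis <- xj %*% wk
  f <- proj %*% wk                         # F = t(Y) X from the last pass
  res <- pca_result(basis, vals, backproj = f, method = "mpowit", v = v,
                    trace = trace,
                    dataloads = list(iteration_passes = loads_iter,
                                     per_iteration = provider$M,
                                     total = dataloads(provider) - loads0))
  if (scaling == "eigs") {
    res$whitened <- sweep(res$basis, 2L, sqrt(pmax(vals, 1e-300)), `/`)
  }
  res
}
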