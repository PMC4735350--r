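#' Initialize or extend a block Krylov state
#'
#' The Krylov subspace `Kr = [X_0, X_1, ..., X_j]` is generated from an
#' initial block `X_0 = Y %*% F_0` (`F_0` standard Gaussian, Mp x b) or a
#' warm-start basis, with each new block
#' `X_j = Y %*% t(t(X_{j-1}) %*% Y) = sum_i Y_i %*% t(t(X_{j-1}) %*% Y_i)`
#' (one dataload per subject per block in unstacked mode).
#'
#' @param state A `krylov_state` from a previous call, or `NULL` to
#'   initialize.
#' @param provider A [group_provider()].
#' @param b Block length (initialization only).
#' @param init `NULL` for random initialization, or a matrix / [pca_result()]
#'   whose basis seeds `X_0` (then `b` is its column count).
#' @param seed Seed for the Gaussian `F_0` (initialization only).
#' @return A `krylov_state`: `blocks` (list of v x b matrices), `b`, `j`
#'   (block count minus one).
#' @export
extend_krylov <- function(state = NULL, provider, b = 170L, init = NULL,
                          seed = NULL) {
  stopifnot(inherits(provider, "group_provider"))
  if (is.null(state)) {
    if (is.null(init)) {
      if (!is.null(seed)) set.seed(seed)
      f0 <- matrix(stats::rnorm(provider$M * provider$p * b),
                   provider$M * provider$p, b)
      x0 <- expand_time(provider, f0)
    } else {
      x0 <- if (inherits(init, "pca_result")) init$basis else as.matrix(init)
      if (nrow(x0) != provider$v) stop("warm-start basis has wrong row count")
      b <- ncol(x0)
    }
    assert_finite(x0, "Krylov block")
    return(structure(list(blocks = list(x0), b = as.integer(b), j = 0L),
                     class = "krylov_state"))
  }
  stopifnot(inherits(state, "krylov_state"))
  xprev <- state$blocks[[length(state$blocks)]]
  xnew <- cov_apply(provider, xprev)
  if (!all(is.finite(xnew))) {
    stop("non-finite entries in Krylov block (unnormalized powering overflow); rescale the data")
  }
  state$blocks <- c(state$blocks, list(xnew))
  state$j <- state$j + 1L
  state
}

#' Ritz values of the current Krylov subspace
#'
#' Assembles `Kr`, orthonormalizes it with an economy QR (dropping
#' numerically dependent columns with a warning), projects the data onto it
#' (`F = t(Y) %*% chi`, one dataload per subject), and takes the economy
#' SVD of `F`. The singular values satisfy `s^2 / (v - 1) = lambda` for the
#' corresponding Ritz eigenvalue estimates, which never exceed the exact
#' eigenvalues.
#'
#' @param state A `krylov_state`.
#' @param provider A [group_provider()].
#' @param k Number of leading singular values to report.
#' @return List with `singular_values` (top-k, descending), `chi`
#'   (orthonormal Kr basis), `w` (right factor rotating `chi` onto Ritz
#'   vectors), `fmat` (the projected `F = t(Y) %*% chi`).
#' @export
ritz_values <- function(state, provider, k) {
  stopifnot(inherits(state, "krylov_state"), inherits(provider, "group_provider"))
  kr <- do.call(cbind, state$blocks)
  if (ncol(kr) > provider$v) stop("(j+1)*b exceeds v; Krylov basis cannot be orthonormal")
  qrd <- qr(kr)
  rk <- qrd$rank
  if (rk < ncol(kr)) {
    warning(sprintf("Krylov matrix is rank deficient (%d < %d); dropping dependent columns",
                    rk, ncol(kr)))
  }
  chi <- qr.Q(qrd)[, seq_len(rk), drop = FALSE]
  fmat <- project_time(provider, chi)
  sv <- svd(fmat)
  list(singular_values = sv$d[seq_len(min(k, length(sv$d)))],
       chi = chi, w = sv$v, fmat = fmat, fleft = sv$u, d = sv$d)
}

#' Convergence-checked randomized block Lanczos group PCA
#'
#' Randomized block Lanczos ("Large PCA") with an explicit convergence
#' check: the Krylov basis is grown to `j0` blocks, then one block at a
#' time, re-estimating the top-k singular values after each extension and
#' stopping when the L2 norm of their successive difference drops below
#' `tol`. With a warm start (an SVP or STP result) the initial block is the
#' warm basis and `j0 = 1`. With `tol = Inf` the solver stops at the first
#' check, reproducing the fixed-j variant.
#'
#' In unstacked mode the convergence-checked run costs
#' `j*2M - j0*M + 2M` dataloads for final block count j (each extension is
#' one pass, each check one more).
#'
#' @param provider A [group_provider()].
#' @param k Number of components.
#' @param b Block length (default 170).
#' @param j0 Blocks built before the first convergence check (default 6;
#'   use 1 with a warm start).
#' @param tol Convergence tolerance on the successive top-k singular-value
#'   difference (default 1e-6); `relative = TRUE` divides by the current
#'   norm.
#' @param max_j Maximum number of blocks.
#' @param init `NULL` (random), or an SVP/STP [pca_result()] (or matrix)
#'   used as `X_0`.
#' @param seed Seed for the random initialization.
#' @param relative Use a relative convergence norm (default absolute).
#' @return A [pca_result()] with method `"large_pca"`; `trace` holds the
#'   per-check singular-value vectors and difference norms.
#' @export
large_pca <- function(provider, k, b = 170L, j0 = NULL, tol = 1e-6,
                      max_j = 30L, init = NULL, seed = NULL,
                      relative = FALSE) {
  stopifnot(inherits(provider, "group_provider"))
  k <- as.integer(k)
  if (tol <= 0) stop("tol must be positive")
  j0 <- as.integer(j0 %||% (if (is.null(init)) 6L else 1L))
  loads0 <- dataloads(provider)
  state <- extend_krylov(NULL, provider, b = b, init = init, seed = seed)
  b_eff <- state$b
  if (k > b_eff) stop("k must be <= the block length")
  while (state$j < j0) {
    if ((state$j + 2L) * b_eff > provider$v) {
      warning("Krylov basis would exceed v columns before j0; stopping growth early")
      break
    }
    state <- extend_krylov(state, provider)
  }
  singular_history <- list()
  diff_norms <- numeric(0)
  rz <- ritz_values(state, provider, k)
  singular_history[[1L]] <- rz$singular_values
  converged <- is.infinite(tol)
  while (!converged) {
    if (state$j >= max_j) {
      err <- structure(
        class = c("grouppca_nonconvergence", "error", "condition"),
        list(message = sprintf("large_pca did not converge within %d blocks", max_j),
             call = sys.call(-1),
             trace = list(singular_history = singular_history,
                          diff_norms = diff_norms)))
      stop(err)
    }
    if ((state$j + 2L) * b_eff > provider$v) {
      warning("Krylov basis reached the v-column limit before meeting tol; returning last estimate")
      break
    }
    state <- extend_krylov(state, provider)
    rz <- ritz_values(state, provider, k)
    n <- length(singular_history)
    singular_history[[n + 1L]] <- rz$singular_values
    d <- l2norm(rz$singular_values - singular_history[[n]])
    if (relative) d <- d / max(l2norm(rz$singular_values), 1e-300)
    diff_norms <- c(diff_norms, d)
    converged <- d < tol
  }
  vals <- (rz$d^2 / (provider$v - 1))[seq_len(k)]
  basis <- rz$chi %*% rz$w[, seq_len(k), drop = FALSE]
  f <- rz$fleft[, seq_len(k), drop = FALSE]
  trace <- list(singular_history = singular_history, diff_norms = diff_norms,
                converged = converged, iterations = state$j,
                blocks_used = state$j + 1L)
  pca_result(basis, vals, backproj = f, method = "large_pca", v = provider$v,
             trace = trace,
             dataloads = list(total = dataloads(provider) - loads0))
}
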