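#' Group PCA result container
#'
#' All group-level solvers in this package return a `pca_result`: the top-k
#' orthonormal spatial basis of the concatenated data `Y = [Y_1 ... Y_M]`
#' (`v` rows), the corresponding eigenvalues of `C = t(Y) %*% Y / (v - 1)`,
#' a whitened copy of the basis scaled to unit sample variance, and the
#' back-projection eigenvector matrix `F` (`M * p` rows, unit-norm columns)
#' that downstream back-reconstruction needs.
#'
#' @param basis v x k matrix with orthonormal columns (left singular subspace
#'   of the stacked data).
#' @param eigenvalues Length-k numeric, descending, eigenvalues of the
#'   time-dimension covariance.
#' @param backproj (M*p) x k matrix `F` with unit L2-norm columns, or `NULL`.
#' @param method Character name of the solver that produced the result.
#' @param trace Optional `convergence_trace` (see [mpowit()]).
#' @param v Number of samples (rows of the data) used for the `v - 1`
#'   whitening denominator.
#' @param dataloads Named list of dataload counts observed during the run.
#'
#' @return An object of class `pca_result` with elements `basis`,
#'   `eigenvalues`, `whitened`, `backproj`, `method`, `trace`, `v`,
#'   `dataloads`.
#' @export
pca_result <- function(basis, eigenvalues, backproj = NULL, method = "evd",
                       trace = NULL, v = nrow(basis), dataloads = list()) {
  basis <- as.matrix(basis)
  sgn <- apply(basis, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  basis <- sweep(basis, 2L, sgn, `*`)
  eigenvalues <- as.numeric(eigenvalues)
  eigenvalues[eigenvalues < 0 & eigenvalues > -1e-10] <- 0
  if (any(diff(eigenvalues) > 1e-8 * max(abs(eigenvalues), 1))) {
    stop("eigenvalues must be sorted in descending order")
  }
  if (!is.null(backproj)) {
    backproj <- as.matrix(backproj)
    nrm <- sqrt(colSums(backproj^2))
    nrm[nrm == 0] <- 1
    backproj <- sweep(backproj, 2L, nrm, `/`)
    backproj <- sweep(backproj, 2L, sgn, `*`)
  }
  structure(
    list(
      basis = basis,
      eigenvalues = eigenvalues,
      whitened = basis * sqrt(v - 1),
      backproj = backproj,
      method = method,
      trace = trace,
      v = v,
      dataloads = dataloads
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("Group PCA result (%s): %d components over %d samples\n",
              x$method, k, nrow(x$basis)))
  show <- utils::head(x$eigenvalues, 5L)
  cat("  top eigenvalues:", paste(signif(show, 6), collapse = ", "),
      if (k > 5L) "..." else "", "\n")
  if (!is.null(x$trace) && !is.null(x$trace$iterations)) {
    cat(sprintf("  converged: %s after %d iterations\n",
                x$trace$converged, x$trace$iterations))
  }
  if (length(x$dataloads) && isTRUE((x$dataloads$total %||% 0) > 0)) {
    cat("  dataloads:", paste(names(x$dataloads), unlist(x$dataloads),
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @noRd
#' Raw F back-projection matrix t(Y) %*% basis; unit-norm scaling and the
#' sign convention are applied inside pca_result() so F stays consistent
#' with the sign-fixed basis.
make_backproj <- function(provider, basis) {
  project_time(provider, basis)
}

#' Write a PCA result to disk
#'
#' Serializes a [pca_result()] to a single self-describing file using R's
#' native serialization.
#'
#' @param result A `pca_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pca_result <- function(result, path) {
  stopifnot(inherits(result, "pca_result"))
  saveRDS(result, path)
  invisible(path)
}

#' @rdname write_pca_result
#' @export
read_pca_result <- function(path) {
  res <- readRDS(path)
  if (!inherits(res, "pca_result")) stop("file does not contain a pca_result")
  res
}
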