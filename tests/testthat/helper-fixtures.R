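# Shared fixtures and an independent dense oracle for the solver tests.
# Fixtures are cached per (profile, mode, seed) so the suite builds each once.

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(profile = "tiny", mode = "stacked", seed = 0) {
  key <- paste(profile, mode, seed, sep = "_")
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- default_fixture(profile, mode = mode, seed = seed)
  }
  .fx_cache[[key]]
}

stacked_y <- function(provider) {
  do.call(cbind, lapply(seq_len(provider$M),
                        function(i) subject_matrix(provider, i)))
}

# Independent oracle: SVD of the explicitly stacked matrix (a different
# LAPACK route than the package's covariance-EVD paths).
dense_oracle <- function(provider, k) {
  y <- stacked_y(provider)
  sv <- svd(y, nu = k, nv = 0)
  list(eigenvalues = (sv$d^2 / (provider$v - 1))[seq_len(k)],
       basis = sv$u[, seq_len(k), drop = FALSE])
}

eig_err <- function(result, oracle) {
  sqrt(sum((result$eigenvalues - oracle$eigenvalues)^2))
}

max_angle <- function(result, oracle) {
  max(principal_angles(result$basis, oracle$basis))
}

# Small noiseless group with a zero-mean planted basis; provider built on the
# raw subject matrices (no first-stage reduction), group spectrum = M * spectrum.
noiseless_group <- function(v = 300, t = 12, M = 3, r = 5,
                            spectrum = c(9, 7, 5, 3, 1), seed = 42,
                            mode = "stacked") {
  gen <- generate_group(v, t, M, r, spectrum = spectrum, noise_sd = 0,
                        seed = seed)
  list(provider = group_provider(gen$subjects, mode = mode),
       truth = gen$truth)
}
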