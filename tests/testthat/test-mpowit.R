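test_that("orth_evd returns an orthonormal basis for the same column space", {
  set.seed(25)
  m <- matrix(rnorm(500 * 40), 500, 40)
  q <- orth_evd(m)
  expect_lt(max(abs(crossprod(q) - diag(40))), 1e-10)
  q_oracle <- qr.Q(qr(m))
  expect_lt(max(principal_angles(q, q_oracle)), 1e-10)

  # single column: plain L2 normalization
  x <- matrix(rnorm(30))
  expect_equal(as.vector(abs(orth_evd(x))), as.vector(abs(x)) / sqrt(sum(x^2)),
               tolerance = 1e-12)

  # already orthonormal input stays orthonormal and in-span
  q2 <- orth_evd(q)
  expect_lt(max(abs(crossprod(q2) - diag(40))), 1e-10)
  expect_lt(max(principal_angles(q2, q)), 1e-10)

  # rank-deficient input: dependent columns dropped with a warning
  md <- cbind(m[, 1:5], m[, 1:2])
  expect_warning(qd <- orth_evd(md), "dependent")
  expect_equal(ncol(qd), 5L)
  expect_lt(max(principal_angles(qd, m[, 1:5])), 1e-7)
})

test_that("power iteration finds the dominant eigenpair", {
  d <- diag(c(4, 1))
  res <- power_iteration(function(x) d %*% x, 2, seed = 26)
  expect_equal(abs(as.vector(res$vector)), c(1, 0), tolerance = 1e-5)
  expect_equal(res$value, 4, tolerance = 1e-8)

  # identity covariance: any start vector is already fixed
  res_id <- power_iteration(function(x) x, 5, seed = 27)
  expect_equal(res_id$iterations, 1L)
  expect_equal(res_id$value, 1, tolerance = 1e-12)

  set.seed(28)
  a <- matrix(rnorm(30 * 30), 30, 30)
  psd <- crossprod(a)
  e <- eigen(psd, symmetric = TRUE)
  res_r <- power_iteration(function(x) psd %*% x, 30, tol = 1e-10, seed = 29)
  expect_equal(res_r$value, e$values[1], tolerance = 1e-8)
  expect_lt(max(principal_angles(res_r$vector, e$vectors[, 1])), 1e-4)
})

test_that("mpowit matches the dense oracle on noisy data", {
  fx <- cached_fixture("tiny")
  oracle <- dense_oracle(fx$provider, 5)
  res <- mpowit(fx$provider, 5, seed = 30)
  expect_lt(eig_err(res, oracle), 1e-6)
  expect_lt(max_angle(res, oracle), 1e-6)
  expect_true(res$trace$converged)
  expect_gte(res$trace$iterations, 2L)             # Lambda_0 = 0 forbids j = 1 stop
  expect_length(res$trace$diff_norms, res$trace$iterations)

  # every per-iteration eigenvalue estimate is a Ritz value: bounded by the oracle
  for (lam in res$trace$eigenvalue_history) {
    expect_true(all(lam <= oracle$eigenvalues + 1e-8))
  }
})

test_that("exact low-rank data is recovered to machine precision even with l = 1", {
  nl <- noiseless_group(v = 250, t = 10, M = 3, r = 5, seed = 31)
  res <- mpowit(nl$provider, 5, l = 1, seed = 32)
  expect_equal(res$eigenvalues, nl$truth$group_spectrum, tolerance = 1e-10)
  expect_lt(max(principal_angles(res$basis, nl$truth$planted_basis)), 1e-8)
})

test_that("the enlarged subspace accelerates convergence", {
  fx <- cached_fixture("small")
  for (k in c(10, 25)) {
    it_l5 <- mpowit(fx$provider, k, l = 5, seed = 33)$trace$iterations
    it_l1 <- mpowit(fx$provider, k, l = 1, seed = 33)$trace$iterations
    expect_lte(it_l5, it_l1)
  }
})

test_that("warm starts from STP converge within three iterations", {
  fx <- cached_fixture("small")
  warm <- stp(fx$provider, 50, k_intermediate = 50, g = 5)
  res <- mpowit(fx$provider, 10, init = warm, seed = 34)
  expect_lte(res$trace$iterations, 3L)
  oracle <- dense_oracle(fx$provider, 10)
  expect_lt(eig_err(res, oracle), 1e-6)
})

test_that("orthonormalization backend does not change the fixed point", {
  fx <- cached_fixture("tiny")
  r_evd <- mpowit(fx$provider, 5, seed = 35, orth = "evd")
  r_qr <- mpowit(fx$provider, 5, seed = 35, orth = "qr")
  expect_lt(max(abs(r_evd$eigenvalues - r_qr$eigenvalues)), 1e-8)
})

test_that("an oversized projecting subspace is reduced with a warning", {
  fx <- cached_fixture("tiny")                     # min(v, Mp) = 40
  expect_warning(res <- mpowit(fx$provider, 10, l = 5, seed = 36),
                 "reducing l")
  expect_length(res$eigenvalues, 10L)
})

test_that("the verbatim eigenvalue scaling is available behind a flag", {
  fx <- cached_fixture("tiny")
  r_uv <- mpowit(fx$provider, 5, seed = 37)
  r_eig <- mpowit(fx$provider, 5, seed = 37, scaling = "eigs")
  expect_equal(r_uv$basis, r_eig$basis)
  expect_equal(colSums(r_eig$whitened^2), 1 / r_eig$eigenvalues,
               tolerance = 1e-8)
  expect_lt(max(abs(crossprod(r_uv$whitened) / (r_uv$v - 1) - diag(5))), 1e-6)
})
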