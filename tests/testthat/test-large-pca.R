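test_that("krylov blocks follow the covariance power recursion", {
  nl <- noiseless_group(v = 200, t = 8, M = 2, r = 3, spectrum = c(4, 2, 1),
                        seed = 16)
  pr <- nl$provider
  y <- do.call(cbind, lapply(1:2, function(i) subject_matrix(pr, i)))
  st <- extend_krylov(NULL, pr, b = 4, seed = 17)
  st <- extend_krylov(st, pr)
  st <- extend_krylov(st, pr)
  cyy <- tcrossprod(y)
  for (j in 2:3) {
    expected <- cyy %*% st$blocks[[j - 1]]
    expect_lt(max(abs(st$blocks[[j]] - expected)) / max(abs(expected)), 1e-10)
  }
  expect_equal(st$j, 2L)
})

test_that("ritz singular values match sqrt((v-1) lambda) on exact low-rank data", {
  nl <- noiseless_group(v = 200, t = 8, M = 2, r = 3, spectrum = c(4, 2, 1),
                        seed = 18)
  pr <- nl$provider
  st <- extend_krylov(NULL, pr, b = 3, seed = 19)
  st <- extend_krylov(st, pr)
  rz <- suppressWarnings(ritz_values(st, pr, 3))
  expect_equal(rz$singular_values,
               sqrt((pr$v - 1) * nl$truth$group_spectrum), tolerance = 1e-8)

  # duplicated blocks span the same space, so Ritz values are unchanged
  st2 <- st
  st2$blocks <- c(st$blocks, st$blocks)
  rz2 <- suppressWarnings(ritz_values(st2, pr, 3))
  expect_equal(rz2$singular_values, rz$singular_values, tolerance = 1e-8)
})

test_that("ritz estimates satisfy the Rayleigh-Ritz bound against the dense oracle", {
  fx <- cached_fixture("tiny")
  pr <- fx$provider
  oracle <- dense_oracle(pr, 5)
  st <- extend_krylov(NULL, pr, b = 8, seed = 20)
  for (j in 1:3) {
    st <- extend_krylov(st, pr)
    rz <- suppressWarnings(ritz_values(st, pr, 5))
    expect_true(all(rz$singular_values^2 / (pr$v - 1) <=
                      oracle$eigenvalues + 1e-8))
  }
})

test_that("large_pca matches the dense oracle and records its trace", {
  fx <- cached_fixture("tiny")
  oracle <- dense_oracle(fx$provider, 5)
  res <- suppressWarnings(large_pca(fx$provider, 5, b = 15, j0 = 3, seed = 21))
  expect_lt(eig_err(res, oracle), 1e-6)
  expect_lt(max_angle(res, oracle), 1e-5)
  expect_true(res$trace$converged)
  expect_length(res$trace$diff_norms, length(res$trace$singular_history) - 1L)

  # growing the subspace never loses captured variance
  sums <- vapply(res$trace$singular_history,
                 function(s) sum(s^2 / (fx$provider$v - 1)), numeric(1))
  expect_true(all(diff(sums) >= -1e-10))
})

test_that("infinite tolerance reproduces the fixed-j variant", {
  fx <- cached_fixture("tiny")
  res <- suppressWarnings(large_pca(fx$provider, 5, b = 15, j0 = 3, tol = Inf,
                                    seed = 22))
  expect_length(res$trace$singular_history, 1L)
  expect_equal(res$trace$blocks_used, 4L)          # j0 + 1 blocks, no growth
})

test_that("warm starts converge with fewer blocks than random initialization", {
  fx <- cached_fixture("small")
  warm <- stp(fx$provider, 50, k_intermediate = 50, g = 5)
  cold <- suppressWarnings(large_pca(fx$provider, 10, seed = 23))
  hot <- suppressWarnings(large_pca(fx$provider, 10, init = warm, seed = 23))
  expect_lt(hot$trace$blocks_used, cold$trace$blocks_used)
  oracle <- dense_oracle(fx$provider, 10)
  expect_lt(eig_err(hot, oracle), 1e-6)
})

test_that("non-convergence raises an error carrying the trace", {
  fx <- cached_fixture("tiny")
  err <- tryCatch(
    suppressWarnings(large_pca(fx$provider, 5, b = 8, j0 = 1, tol = 1e-300,
                               max_j = 2, seed = 24)),
    grouppca_nonconvergence = function(e) e)
  expect_s3_class(err, "grouppca_nonconvergence")
  expect_true(length(err$trace$singular_history) >= 1L)
})
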