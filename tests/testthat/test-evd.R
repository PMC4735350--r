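make_random_provider <- function(M, v = 80, p = 6, seed = 9, mode = "stacked") {
  set.seed(seed)
  mats <- lapply(seq_len(M), function(i) {
    center_columns(matrix(rnorm(v * p), v, p))
  })
  group_provider(mats, mode = mode)
}

test_that("cross_cov_time equals the dense stacked covariance", {
  pr1 <- make_random_provider(1)
  y1 <- subject_matrix(pr1, 1)
  expect_lt(max(abs(cross_cov_time(pr1) - crossprod(y1) / (pr1$v - 1))), 1e-12)
  ev <- eigen(cross_cov_time(pr1), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)                       # PSD

  # duplicated subject: all four blocks equal
  set.seed(10)
  y <- center_columns(matrix(rnorm(50 * 4), 50, 4))
  prd <- group_provider(list(y, y))
  cd <- cross_cov_time(prd)
  blk <- cd[1:4, 1:4]
  expect_equal(cd[1:4, 5:8], blk, tolerance = 1e-12)
  expect_equal(cd[5:8, 5:8], blk, tolerance = 1e-12)

  pr4 <- make_random_provider(4)
  ystack <- do.call(cbind, lapply(1:4, function(i) subject_matrix(pr4, i)))
  expect_lt(max(abs(cross_cov_time(pr4) - crossprod(ystack) / (pr4$v - 1))), 1e-12)
  expect_equal(cross_cov_time(pr4), t(cross_cov_time(pr4)))
})

test_that("cross_cov_time in unstacked mode holds two subjects at a time", {
  pr <- make_random_provider(4, mode = "unstacked")
  reset_dataloads(pr)
  cmat <- cross_cov_time(pr)
  # diagonal blocks: M loads; off-diagonal pairs: M(M-1)/2 extra loads of y_j
  expect_equal(dataloads(pr), 4L + 4L * 3L / 2L)
  expect_equal(dim(cmat), c(24L, 24L))
})

test_that("voxel_cov_sum shares its nonzero spectrum with the time path", {
  pr <- make_random_provider(3, v = 40, p = 5)
  pru <- make_random_provider(3, v = 40, p = 5, mode = "unstacked")
  reset_dataloads(pru)
  cv <- voxel_cov_sum(pru)
  expect_equal(dataloads(pru), 3L)                 # one load per subject
  expect_equal(cv, t(cv))
  y1 <- subject_matrix(pr, 1)
  pr1 <- group_provider(list(y1))
  expect_lt(max(abs(voxel_cov_sum(pr1) - tcrossprod(y1) / (pr1$v - 1))), 1e-12)

  ev_v <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev_t <- eigen(cross_cov_time(pr), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev_v[1:15], ev_t[1:15], tolerance = 1e-8)
})

test_that("covariance caps advise iterative solvers", {
  pr <- make_random_provider(2)
  expect_error(cross_cov_time(pr, cap = 5), "mpowit|large_pca")
  expect_error(voxel_cov_sum(pr, cap = 5), "mpowit|large_pca")
  expect_error(evd_group_pca(pr, 3, cap = 5), "mpowit|large_pca")
})

test_that("evd_group_pca recovers planted structure and satisfies PCAResult invariants", {
  nl <- noiseless_group()
  res <- evd_group_pca(nl$provider, 5)
  expect_equal(res$eigenvalues, nl$truth$group_spectrum, tolerance = 1e-9)
  expect_lt(max(principal_angles(res$basis, nl$truth$planted_basis)), 1e-8)

  expect_lt(max(abs(crossprod(res$basis) - diag(5))), 1e-8)
  expect_lt(max(abs(crossprod(res$whitened) / (res$v - 1) - diag(5))), 1e-6)
  expect_equal(colSums(res$backproj^2), rep(1, 5), tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))

  # k = 1 matches the dominant left singular vector up to sign
  sv <- svd(do.call(cbind, lapply(1:3, function(i) subject_matrix(nl$provider, i))),
            nu = 1, nv = 0)
  r1 <- evd_group_pca(nl$provider, 1)
  expect_lt(min(sum((r1$basis - sv$u)^2), sum((r1$basis + sv$u)^2)), 1e-12)

  expect_error(evd_group_pca(nl$provider, 20), "rank")
})

test_that("time and voxel EVD paths agree", {
  pr <- make_random_provider(3, v = 50, p = 6, seed = 11)
  rt <- evd_group_pca(pr, 6, path = "time")
  rv <- evd_group_pca(pr, 6, path = "voxel")
  expect_lt(max(abs(rt$eigenvalues - rv$eigenvalues)), 1e-9)
  expect_lt(max(principal_angles(rt$basis, rv$basis)), 1e-6)
  expect_lt(max(abs(abs(colSums(rt$backproj * rv$backproj)) - 1)), 1e-6)
})
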