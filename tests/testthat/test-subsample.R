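test_that("build_scheme splits voxels by lattice parity", {
  full <- brain_mask(array(TRUE, c(4, 4, 4)))
  sch <- build_scheme(full, 2)
  expect_equal(length(sch$odd_index_set), 8L)      # 2^3 all-odd sites
  expect_equal(length(sch$even_index_set), 8L)
  expect_length(intersect(sch$odd_index_set, sch$even_index_set), 0L)

  expect_error(build_scheme(full, 1), "no subsampling")

  set.seed(12)
  msk <- brain_mask(array(runif(5 * 6 * 4) > 0.4, c(5, 6, 4)))
  got <- build_scheme(msk, 2)
  coords <- which(msk$flags, arr.ind = TRUE)
  brute_odd <- which(apply(coords, 1, function(xyz) all(xyz %% 2 == 1)))
  brute_even <- which(apply(coords, 1, function(xyz) all(xyz %% 2 == 0)))
  expect_equal(got$odd_index_set, brute_odd)
  expect_equal(got$even_index_set, brute_even)

  # non-spatial fallback: strided with offsets 0 and depth-1
  s <- build_scheme(10L, 2)
  expect_equal(s$odd_index_set, c(1L, 3L, 5L, 7L, 9L))
  expect_equal(s$even_index_set, c(2L, 4L, 6L, 8L, 10L))
})

test_that("svp recovers smooth noiseless structure", {
  gen <- generate_group(600, 12, 3, 4, spectrum = c(8, 5, 3, 1), noise_sd = 0,
                        smoothness = 2, seed = 13)
  pr <- group_provider(gen$subjects)
  flags <- array(FALSE, gen$truth$grid_shape); flags[1:600] <- TRUE
  sch <- build_scheme(brain_mask(flags), 2)
  res <- svp(pr, 4, k_intermediate = 12, scheme = sch)
  expect_lt(max(principal_angles(res$basis, gen$truth$planted_basis)), 1e-6)
  expect_equal(res$eigenvalues, gen$truth$group_spectrum, tolerance = 1e-8)
})

test_that("svp is lossless when odd and even voxel rows carry the same data", {
  set.seed(14)
  half <- matrix(rnorm(100 * 8), 100, 8)
  mats <- lapply(1:3, function(i) {
    m <- matrix(0, 200, 8)
    m[seq(1, 199, 2), ] <- half %*% qr.Q(qr(matrix(rnorm(64), 8, 8)))
    m[seq(2, 200, 2), ] <- m[seq(1, 199, 2), ]
    center_columns(m)
  })
  pr <- group_provider(mats)
  oracle <- evd_group_pca(pr, 5)
  res <- svp(pr, 5, k_intermediate = 12)           # strided parity = the duplication
  expect_lt(sqrt(sum((res$eigenvalues - oracle$eigenvalues)^2)), 1e-8)
})

test_that("svp validates its model orders", {
  fx <- cached_fixture("tiny")
  expect_error(svp(fx$provider, 10, k_intermediate = 5), "k must be <=")
  expect_error(svp(fx$provider, 5, k_intermediate = 10000), "exceeds")
})

test_that("stp with a single group equals exact EVD", {
  fx <- cached_fixture("tiny")
  oracle <- evd_group_pca(fx$provider, 8)
  res <- stp(fx$provider, 8, k_intermediate = 40, g = fx$M)
  expect_lt(sqrt(sum((res$eigenvalues - oracle$eigenvalues)^2)), 1e-8)
  expect_lt(max(principal_angles(res$basis, oracle$basis)), 1e-6)
})

test_that("stp handles the MIGP special case g = 1 and group-order invariance", {
  nl <- noiseless_group(v = 250, t = 10, M = 4, r = 4,
                        spectrum = c(6, 4, 2, 1), seed = 15)
  migp <- stp(nl$provider, 4, k_intermediate = 8, g = 1)
  expect_lt(max(principal_angles(migp$basis, nl$truth$planted_basis)), 1e-8)
  expect_equal(migp$eigenvalues, nl$truth$group_spectrum, tolerance = 1e-9)

  shuf <- stp(nl$provider, 4, k_intermediate = 8, g = 1, shuffle = TRUE, seed = 3)
  expect_equal(shuf$eigenvalues, migp$eigenvalues, tolerance = 1e-9)
})

test_that("stp lowers an infeasible k_intermediate with a warning", {
  fx <- cached_fixture("tiny")
  expect_warning(res <- stp(fx$provider, 5, k_intermediate = 25, g = 2),
                 "lowering k_intermediate")
  expect_length(res$eigenvalues, 5L)
})

test_that("stp is single-pass and svp uses two passes for the subspace", {
  fx <- cached_fixture("tiny", "unstacked")
  pr <- fx$provider
  reset_dataloads(pr)
  res <- stp(pr, 5, k_intermediate = 20, g = 2)
  expect_equal(dataloads(pr), pr$M)                # exactly one pass
  expect_equal(res$dataloads$pass, pr$M)
  reset_dataloads(pr)
  rv <- svp(pr, 5, k_intermediate = 20, scheme = fx$scheme)
  expect_equal(rv$dataloads$subspace, 2L * pr$M)   # subspace in two passes
  expect_equal(dataloads(pr), 3L * pr$M)           # + eigenvalue/F read-out pass
})

test_that("subsampled eigenvalue estimates obey the Rayleigh-Ritz bound", {
  for (fx in list(cached_fixture("tiny"), cached_fixture("small"))) {
    oracle <- dense_oracle(fx$provider, 10)
    kint <- min(50L, fx$M * fx$p,
                length(fx$scheme$odd_index_set), length(fx$scheme$even_index_set))
    sres <- suppressWarnings(stp(fx$provider, 10, k_intermediate = kint, g = 5))
    vres <- svp(fx$provider, 10, k_intermediate = kint, scheme = fx$scheme)
    expect_true(all(sres$eigenvalues <= oracle$eigenvalues + 1e-8))
    expect_true(all(vres$eigenvalues <= oracle$eigenvalues + 1e-8))
  }
})
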