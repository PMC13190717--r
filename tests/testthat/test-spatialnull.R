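# spatial weights, Moran's I, the Moran eigenbasis, spectrum-preserving
# surrogates and the map-similarity test

test_that("inverse-squared-distance weights match hand arithmetic", {
  g2 <- volume_grid(c(2, 1, 1), 2)
  w2 <- build_weights(g2, array(TRUE, c(2, 1, 1)))
  expect_equal(w2$w[1, 2], 0.25)
  expect_equal(diag(w2$w), c(0, 0))

  g3 <- volume_grid(c(3, 1, 1), 3)
  w3 <- build_weights(g3, array(TRUE, c(3, 1, 1)))
  expect_equal(w3$w[1, 2], 1 / 9)
  expect_equal(w3$w[2, 3], 1 / 9)
  expect_equal(w3$w[1, 3], 1 / 36)

  expect_error(build_weights(g3, array(TRUE, c(3, 1, 1)), voxel_cap = 2),
               class = "tremornet_resource_error")
})

test_that("Moran's I matches a brute-force double sum and its permutation null", {
  g <- volume_grid(c(3, 3, 1), 2)
  msk <- array(TRUE, c(3, 3, 1))
  w <- build_weights(g, msk)
  set.seed(5)
  x <- rnorm(9)
  # independent brute-force oracle
  z <- x - mean(x)
  num <- 0
  for (i in 1:9) for (j in 1:9) num <- num + w$w[i, j] * z[i] * z[j]
  I_oracle <- (9 / sum(w$w)) * num / sum(z^2)
  expect_equal(morans_i(x, w), I_oracle, tolerance = 1e-12)

  # smooth monotone gradient along x is positively autocorrelated
  grad <- grid_coordinates(g)[, 1]
  expect_gt(morans_i(grad, w), 0)

  set.seed(6)
  Is <- replicate(4000, morans_i(sample(x), w))
  expect_lt(abs(mean(Is) + 1 / 8), 0.01)

  expect_error(morans_i(rep(1, 9), w), class = "tremornet_constant_map")
})

test_that("Moran eigenbasis is orthonormal, centred, and satisfies the MEM identity", {
  g <- volume_grid(c(4, 4, 1), 3)
  w <- build_weights(g, array(TRUE, c(4, 4, 1)))
  b <- moran_eigenbasis(w)
  expect_equal(ncol(b$vectors), 15)
  G <- crossprod(b$vectors)
  expect_lt(max(abs(G - diag(15))), 1e-8)
  expect_lt(max(abs(colSums(b$vectors))), 1e-8)
  for (k in c(1, 7, 15))
    expect_equal(morans_i(b$vectors[, k], w), (b$n / b$s0) * b$values[k],
                 tolerance = 1e-6)
})

test_that("MSR surrogates preserve moments exactly and the Moran spectrum", {
  g <- volume_grid(c(8, 8, 5), 4)
  msk <- synth_brain_mask(g, 0.95, 2)
  w <- build_weights(g, msk)
  b <- moran_eigenbasis(w)
  x <- map_values(smooth_map(g, msk, fwhm = 8, seed = 31))
  s <- msr_surrogates(x, b, 100, seed = 4)
  expect_lt(max(abs(colMeans(s) - mean(x))), 1e-10)
  expect_lt(max(abs(apply(s, 2, sd) - sd(x))), 1e-10)
  I_obs <- morans_i(x, w)
  I_surr <- mean(apply(s, 2, morans_i, weights = w))
  expect_lt(abs(I_surr - I_obs), max(0.1 * abs(I_obs), 0.01))
  expect_identical(msr_surrogates(x, b, 5, seed = 4), s[, 1:5] * 1)
})

test_that("similarity test: rank invariance, symmetric rho, coordinate-scale invariance", {
  g <- volume_grid(c(8, 8, 5), 4)
  msk <- synth_brain_mask(g, 0.95, 2)
  a <- smooth_map(g, msk, fwhm = 8, seed = 51)
  expect_equal(similarity_test(a, a, n_surr = 50, seed = 1)$rho_obs, 1)
  mono <- map_with_values(a, exp(2 * map_values(a)) + 1)
  expect_equal(similarity_test(a, mono, n_surr = 50, seed = 1)$rho_obs, 1)

  b <- smooth_map(g, msk, fwhm = 8, seed = 52)
  r1 <- similarity_test(a, b, n_surr = 200, seed = 7, permuted_side = "a")
  r2 <- similarity_test(a, b, n_surr = 200, seed = 7, permuted_side = "b")
  expect_equal(r1$rho_obs, r2$rho_obs)

  # scaling all coordinates leaves the test invariant (weights scale by k^-2)
  g_half <- volume_grid(c(8, 8, 5), 2)
  a2 <- brain_map(g_half, a$data, msk); b2 <- brain_map(g_half, b$data, msk)
  r3 <- similarity_test(a2, b2, n_surr = 200, seed = 7, permuted_side = "a")
  expect_equal(r3$rho_obs, r1$rho_obs)
  expect_equal(r3$p, r1$p, tolerance = 1e-12)

  cm <- map_with_values(a, rep(2, sum(msk)))
  expect_error(similarity_test(cm, b, n_surr = 10, seed = 1),
               class = "tremornet_constant_map")
})

test_that("zero surrogate exceedances are reported as an upper bound", {
  g <- volume_grid(c(8, 8, 5), 4)
  msk <- synth_brain_mask(g, 0.95, 2)
  a <- smooth_map(g, msk, fwhm = 8, seed = 61)
  r <- similarity_test(a, a, n_surr = 100, seed = 2)
  expect_true(r$p_upper_bound)
  expect_equal(r$p, 1 / 100)
})
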