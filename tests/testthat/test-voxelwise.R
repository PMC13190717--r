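# mass-univariate stats: subtraction maps, sign-flip permutation t-test with
# exact enumeration, covariate regression

test_that("difference maps subtract Off from On and invert", {
  sim <- simulate_cohort(small_config(), seed = 2)
  d <- diff_maps(sim$cohort)
  p1 <- sim$cohort$patients[[1]]
  expect_equal(map_values(d[[1]]),
               map_values(p1$on_map) - map_values(p1$off_map), tolerance = 1e-12)
  expect_equal(map_values(d[[1]]) + map_values(p1$off_map),
               map_values(p1$on_map), tolerance = 1e-12)

  same <- structure(list(patients = list(list(on_map = p1$on_map, off_map = p1$on_map))),
                    class = "tn_cohort")
  expect_true(all(map_values(diff_maps(same)[[1]]) == 0))

  other <- p1$on_map; other$grid$origin_mm <- other$grid$origin_mm + 1
  bad <- structure(list(patients = list(list(on_map = other, off_map = p1$off_map))),
                   class = "tn_cohort")
  expect_error(diff_maps(bad), class = "tremornet_alignment_error")
})

test_that("one-sample permutation t matches a brute-force enumeration oracle", {
  g <- tiny_grid(c(3, 3, 2), 2)
  set.seed(8)
  maps <- lapply(1:4, function(i) brain_map(g, array(rnorm(18), c(3, 3, 2))))
  Y <- do.call(rbind, lapply(maps, map_values))
  n <- 4

  # independent oracle: enumerate all 16 sign patterns explicitly
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1), c(1, -1)))
  t_of <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  t_all <- matrix(0, 16, ncol(Y))
  for (s in 1:16) for (v in seq_len(ncol(Y))) t_all[s, v] <- t_of(signs[s, ] * Y[, v])
  t_obs_oracle <- apply(Y, 2, t_of)
  max_abs <- apply(abs(t_all), 1, max)
  p_oracle <- vapply(abs(t_obs_oracle), function(t0) mean(max_abs >= t0), numeric(1))

  res <- one_sample_perm_t(maps, n_perm = 16, seed = 1)
  expect_true(res$exact)
  expect_equal(map_values(res$stat), t_obs_oracle, tolerance = 1e-10)
  expect_equal(map_values(res$p_fwe), p_oracle, tolerance = 1e-12)
  expect_equal(min(map_values(res$p_fwe)) >= 1 / 16, TRUE)

  # enumeration is seed-independent
  res2 <- one_sample_perm_t(maps, n_perm = 100, seed = 999)
  expect_equal(map_values(res2$p_fwe), map_values(res$p_fwe), tolerance = 1e-12)
})

test_that("zero-variance voxels are excluded and sign-flip antisymmetry holds", {
  g <- tiny_grid(c(3, 3, 2), 2)
  set.seed(9)
  base <- array(rnorm(18), c(3, 3, 2))
  maps <- lapply(1:5, function(i) {
    arr <- base + array(rnorm(18), c(3, 3, 2))
    arr[1, 1, 1] <- 2.5          # identical across subjects
    brain_map(g, arr)
  })
  res <- one_sample_perm_t(maps, n_perm = 32, seed = 1)
  expect_equal(res$n_zero_variance, 1L)
  expect_false(res$stat$mask[1, 1, 1])

  neg <- lapply(maps, function(m) map_with_values(m, -map_values(m)))
  rneg <- one_sample_perm_t(neg, n_perm = 32, seed = 1)
  expect_equal(map_values(rneg$stat), -map_values(res$stat), tolerance = 1e-12)
  expect_equal(map_values(rneg$p_fwe), map_values(res$p_fwe), tolerance = 1e-12)

  # FWE p monotone non-increasing in |t|
  o <- order(abs(map_values(res$stat)))
  expect_true(all(diff(map_values(res$p_fwe)[o]) <= 1e-12))
})

test_that("voxelwise regression recovers a planted covariate pattern and checks designs", {
  g <- tiny_grid(c(6, 6, 4), 2)
  tmpl <- make_template_network(g, data.frame(x = c(-3, 3), y = 0, z = 0,
                                              radius_mm = 3, sign = c(1, -1),
                                              weight = 1), smooth_fwhm_mm = 4)
  cov_x <- c(0.2, 0.9, 1.7, 2.1, 3.3, 4.0, 4.8, 5.5)
  maps <- lapply(cov_x, function(ci)
    map_with_values(tmpl, 2 * ci * map_values(tmpl) + 5))
  res <- voxelwise_regression(maps, cov_x, n_perm = 50, seed = 3)
  tv <- map_values(res$stat)
  ts <- map_values(tmpl)[res$stat$mask[tmpl$mask]]
  expect_true(all(sign(tv[ts != 0]) == sign(ts[ts != 0])))

  expect_error(voxelwise_regression(maps[1:2], cov_x[1:2], 10, 1),
               class = "tremornet_insufficient_data")
  expect_error(voxelwise_regression(maps, rep(1, 8), 10, 1),
               class = "tremornet_degenerate_design")
})

test_that("statmap table reports suprathreshold voxels with world coordinates", {
  sim <- simulate_cohort(small_config(), seed = 6)
  res <- one_sample_perm_t(diff_maps(sim$cohort), n_perm = 300, seed = 2)
  tb <- statmap_table(res, p_threshold = 1)
  expect_equal(nrow(tb), sum(res$stat$mask))
  expect_true(all(tb$p_fwe >= 1 / res$n_permutations))
  i <- which.max(abs(tb$t))
  expect_equal(tb$x_mm[i],
               res$stat$grid$origin_mm[1] + (tb$i[i] - 1) * res$stat$grid$voxel_size_mm[1])
})
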