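# clinical statistics: paired test, relative improvement, confound
# screening, outcome regression, VTA-overlap ROI

# a difference vector with exactly the requested mean and SEM
vector_with_mean_sem <- function(n, mean, sem) {
  contrast <- scale(seq_len(n))[, 1]           # zero mean, unit sample sd
  mean + contrast * sem * sqrt(n)
}

test_that("paired t-test matches its closed-form oracle and t.test", {
  d <- vector_with_mean_sem(14, 11.07, 1.16)
  expect_equal(mean(d), 11.07)
  expect_equal(sd(d) / sqrt(14), 1.16, tolerance = 1e-12)
  off <- rnorm(14) + 20; on <- off - d
  res <- paired_ttest(off, on)
  # independent oracle: base t.test
  tt <- t.test(off, on, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter))
  expect_equal(res$change_on_minus_off, -11.07, tolerance = 1e-12)

  # d and -d give the same two-sided p
  res_neg <- paired_ttest(on, off)
  expect_equal(res_neg$p, res$p, tolerance = 1e-15)

  expect_error(paired_ttest(off, off), class = "tremornet_degenerate_data")
})

test_that("relative improvement handles the boundary cases", {
  expect_equal(relative_improvement(10, 0), 100)
  expect_equal(relative_improvement(7, 7), 0)
  expect_equal(relative_improvement(10, 12), -20)
  expect_warning(out <- relative_improvement(c(10, 0), c(5, 0)),
                 class = "tremornet_undefined_improvement")
  expect_equal(out, c(50, NA))
})

test_that("confound screening isolates a planted driver and flags collinearity", {
  set.seed(13)
  rejected <- 0
  for (r in 1:20) {
    amp <- runif(14, 1.5, 4.5)
    pw <- sample(c(60, 90, 120), 14, replace = TRUE)
    fr <- sample(c(130, 180), 14, replace = TRUE)
    resp <- 2 * amp
    sc <- suppressWarnings(
      screen_confounds(resp, data.frame(amplitude = amp, pulse_width = pw,
                                        frequency = fr)))
    expect_equal(sc$r_squared[sc$parameter == "amplitude"], 1, tolerance = 1e-10)
    expect_true(sc$significant_independent[sc$parameter == "amplitude"])
    rejected <- rejected + sc$significant_independent[sc$parameter == "frequency"]
  }
  expect_lte(rejected, 5)    # unrelated parameter stays mostly non-significant

  dup <- data.frame(a = rnorm(10), b = rnorm(10))
  dup$c <- dup$a
  expect_true(any(is.infinite(
    suppressWarnings(screen_confounds(rnorm(10), dup))$vif)))

  expect_error(screen_confounds(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3),
                                                     c = rnorm(3))),
               class = "tremornet_insufficient_data")
})

test_that("outcome regression: exact fit, R^2 = r^2, orthogonal covariates", {
  set.seed(14)
  z <- rnorm(12)
  imp <- 60 + 9 * z
  expect_equal(suppressWarnings(outcome_regression(imp, z))$r_squared, 1,
               tolerance = 1e-12)

  imp2 <- 60 + 9 * z + rnorm(12, 0, 5)
  fit <- outcome_regression(imp2, z)
  expect_equal(fit$base_model$r_squared, cor(imp2, z)^2, tolerance = 1e-10)

  # covariate orthogonal to both response residual space never lowers R^2
  covar <- data.frame(a = rnorm(12))
  fit2 <- outcome_regression(imp2, z, covariates = covar)
  expect_gte(fit2$r_squared, fit$base_model$r_squared - 1e-12)

  expect_error(outcome_regression(imp2, z, covariates = data.frame(a = z)),
               class = "tremornet_design_error")
})

test_that("VTA-overlap ROI follows the counting rule", {
  sim <- simulate_cohort(noise_free(n = 6), seed = 4)
  co <- sim$cohort
  # all identical VTAs -> ROI equals that VTA (within the analysis mask)
  vta <- co$patients[[1]]$vta_mask
  for (i in seq_along(co$patients)) co$patients[[i]]$vta_mask <- vta
  roi <- vta_overlap_roi(co, min_overlap = 3)
  expect_identical(roi$roi, vta & co$analysis_mask)

  # nested spheres: brute-force voxel counting oracle
  ctr <- c(8, -6, 0)
  radii <- c(12, 9, 6, 4, 4, 4)
  for (i in 1:6) co$patients[[i]]$vta_mask <- tremornet:::sphere_mask(co$grid, ctr, radii[i])
  roi3 <- vta_overlap_roi(co, min_overlap = 3)
  counts <- Reduce(`+`, lapply(co$patients, function(p) p$vta_mask * 1L))
  expect_identical(roi3$roi, (counts >= 3) & co$analysis_mask)
  expect_identical(roi3$roi & tremornet:::sphere_mask(co$grid, ctr, 6), roi3$roi)

  # z-scored uptake has zero mean, unit sd
  expect_equal(mean(roi3$uptake$z), 0, tolerance = 1e-10)
  expect_equal(sd(roi3$uptake$z), 1, tolerance = 1e-10)

  # disjoint VTAs
  for (i in 1:6) co$patients[[i]]$vta_mask <-
    tremornet:::sphere_mask(co$grid, c(-16 + 6 * i, 20, 12), 2)
  expect_error(vta_overlap_roi(co, min_overlap = 3), class = "tremornet_threshold_error")
})
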