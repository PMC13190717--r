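# synthetic cohort generator: template construction, generative identities,
# determinism, and serialization

test_that("template network: unsmoothed spheres, antisymmetry, placement check", {
  g <- tiny_grid(c(10, 10, 10), 2)
  hub <- data.frame(x = 0, y = 0, z = 0, radius_mm = 4, sign = 1, weight = 2)
  tm <- make_template_network(g, hub, smooth_fwhm_mm = 0)
  co <- grid_coordinates(g)
  inside <- rowSums(co^2) <= 16
  expect_equal(as.vector(tm$data), ifelse(inside, 2, 0))

  pair <- data.frame(x = c(-4, 4), y = 0, z = 0, radius_mm = 3,
                     sign = c(1, -1), weight = 1)
  tp <- make_template_network(g, pair, smooth_fwhm_mm = 4)
  expect_equal(sum(tp$data), 0, tolerance = 1e-10)
  expect_true(any(tp$data > 0) && any(tp$data < 0))

  expect_identical(make_template_network(g, pair, 4)$data, tp$data)
  far <- data.frame(x = 500, y = 0, z = 0, radius_mm = 3, sign = 1, weight = 1)
  expect_error(make_template_network(g, far, 0), class = "tremornet_placement_error")
})

test_that("noise-free cohorts satisfy the generative identities exactly", {
  cfg <- noise_free(beta0 = 0, beta1 = 1, g_mean = 50, g_sd = 10)
  sim <- simulate_cohort(cfg, seed = 7)
  co <- sim$cohort; tr <- sim$truth
  Lv <- map_values(tr$local_kernel); Tv <- map_values(tr$template_network)
  for (i in c(1, 4, 8)) {
    p <- tr$patients[i, ]
    d <- map_values(co$patients[[i]]$on_map) - map_values(co$patients[[i]]$off_map)
    expect_equal(d, p$amplitude * cfg$c_L * Lv + p$g * cfg$c_T * Tv, tolerance = 1e-12)
  }
  clin <- clinical_table(co)
  imp <- relative_improvement(clin$trs_off, clin$trs_on)
  expect_equal(imp, tr$patients$g, tolerance = 1e-10)
})

test_that("generator is deterministic and self-consistent under clinical noise 0", {
  sim1 <- simulate_cohort(small_config(), seed = 42)
  sim2 <- simulate_cohort(small_config(), seed = 42)
  expect_identical(sim1$cohort$patients[[3]]$on_map$data,
                   sim2$cohort$patients[[3]]$on_map$data)
  expect_identical(sim1$truth$patients, sim2$truth$patients)

  cfg <- small_config(clinical_noise_sd = 0, trs_noise_sd = 0)
  sim <- simulate_cohort(cfg, seed = 9)
  clin <- clinical_table(sim$cohort)
  imp <- relative_improvement(clin$trs_off, clin$trs_on)
  keep <- imp < 100 - 1e-9          # exclude patients clipped at full response
  fit <- suppressWarnings(summary(lm(imp[keep] ~ sim$truth$patients$g[keep])))
  expect_equal(unname(coef(fit)[2, 1]), cfg$beta1, tolerance = 1e-8)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
})

test_that("amplitude drives VTA-ROI uptake change positively in noise-free cohorts", {
  for (s in c(3, 14, 25)) {
    sim <- simulate_cohort(noise_free(n = 10), seed = s)
    roi <- vta_overlap_roi(sim$cohort, min_overlap = 3)
    clin <- clinical_table(sim$cohort)
    expect_gt(cor(roi$uptake$mean_uptake, clin$amplitude_mA), 0)
  }
})

test_that("cohort write/read round trip restores maps, table and ground truth", {
  sim <- simulate_cohort(small_config(), seed = 5)
  d <- withr::local_tempdir()
  write_cohort(sim$cohort, sim$truth, d)
  clin_file <- read.delim(file.path(d, "clinical.tsv"))
  expect_equal(nrow(clin_file), cohort_size(sim$cohort))
  expect_named(clin_file, c("id", "trs_off", "trs_on", "amplitude_mA",
                            "pulse_width_us", "frequency_Hz"))
  rt <- read_cohort(d)
  expect_equal(cohort_size(rt$cohort), cohort_size(sim$cohort))
  expect_lt(max(abs(rt$cohort$patients[[2]]$off_map$data -
                    sim$cohort$patients[[2]]$off_map$data)), 1e-4)
  expect_identical(rt$cohort$patients[[2]]$vta_mask, sim$cohort$patients[[2]]$vta_mask)
  expect_identical(rt$truth$config_hash, sim$truth$config_hash)
  expect_equal(rt$truth$coefficients$beta1, sim$truth$coefficients$beta1)

  # partial cohorts are rejected
  broken <- sim$cohort
  broken$patients[[1]]$conn_map <- NULL
  expect_error(write_cohort(broken, dir = withr::local_tempdir()),
               class = "tremornet_cohort_error")
})
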