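# shared builders for test fixtures (all generated in code)

tiny_grid <- function(shape = c(8, 8, 8), voxel = 2) volume_grid(shape, voxel)

random_map <- function(grid = tiny_grid(), mask = NULL, seed = 1) {
  set.seed(seed)
  brain_map(grid, array(rnorm(prod(grid$shape)), grid$shape), mask)
}

# smooth Gaussian random field restricted to a mask
smooth_map <- function(grid, mask = NULL, fwhm = 8, seed = 1) {
  set.seed(seed)
  gaussian_smooth(brain_map(grid, array(rnorm(prod(grid$shape)), grid$shape), mask), fwhm)
}

# small cohort config for fast tests
small_config <- function(n = 8, ...) {
  cohort_config(n = n, shape = c(12, 14, 10), voxel_mm = 4,
                hubs = data.frame(x = c(-16, 16, -12, 12), y = c(-8, -8, 16, 16),
                                  z = c(8, 8, -4, -4), radius_mm = c(10, 10, 8, 8),
                                  sign = c(1, 1, -1, -1), weight = c(1, 1, 0.6, 0.6)),
                stim_center_mm = c(8, -6, 0), ...)
}

noise_free <- function(cfg_fun = small_config, ...) {
  cfg_fun(noise_sd = 0, trs_noise_sd = 0, clinical_noise_sd = 0,
          conn_noise_sd = 0, vta_jitter_sd_mm = 0, ...)
}

# world with per-patient smooth connectivity fields and change maps carrying
# a compact planted positive-connectivity effect of strength gamma
make_conn_world <- function(n = 12, seed = 1, gamma = 0, noise_sd = 0.5,
                            all_positive = FALSE) {
  g <- volume_grid(c(10, 10, 8), 4)
  msk <- synth_brain_mask(g, 0.95, 2.5)
  set.seed(seed)
  conn <- lapply(seq_len(n), function(i) {
    f <- smooth_map(g, msk, fwhm = 8, seed = seed * 1000 + i)
    v <- map_values(f) / sd(map_values(f))
    if (all_positive) v <- abs(v) + 0.1
    map_with_values(f, v)
  })
  blob <- tremornet:::sphere_mask(g, c(0, 0, 0), 10) & msk
  amp <- runif(n, 1.5, 4.5)
  delta <- lapply(seq_len(n), function(i) {
    nz <- smooth_map(g, msk, fwhm = 8, seed = seed * 2000 + i)
    nv <- map_values(nz) / sd(map_values(nz)) * noise_sd
    pv <- pmax(map_values(conn[[i]]), 0)
    map_with_values(conn[[i]], gamma * pv * blob[msk] + nv)
  })
  list(grid = g, mask = msk, conn = conn, delta = delta, amp = amp, blob = blob)
}

# paired condition maps carrying a planted covariance pattern P with
# positive per-subject gains
planted_world <- function(n = 8, seed = 2, noise = 0) {
  g <- volume_grid(c(10, 10, 8), 4)
  msk <- synth_brain_mask(g, 0.95, 2.5)
  P <- map_values(smooth_map(g, msk, fwhm = 8, seed = 77))
  P <- P / sqrt(sum(P^2))
  set.seed(seed)
  off <- lapply(seq_len(n), function(i) smooth_map(g, msk, fwhm = 8, seed = 100 + i))
  cs <- runif(n, 0.5, 2)
  on <- lapply(seq_len(n), function(i) {
    v <- map_values(off[[i]]) + cs[i] * P
    if (noise > 0) v <- v + rnorm(length(v), 0, noise)
    map_with_values(off[[i]], v)
  })
  list(on = on, off = off, P = P, cs = cs, grid = g, mask = msk)
}
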