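# Synthetic cohorts with the statistical structure the analysis assumes:
# smooth Gaussian random fields, a hub-based template tremor network, an
# amplitude-driven local stimulation effect, a network-aligned treatment
# effect coupled to clinical improvement, and spherical VTAs.  Ground truth
# (planted template, gains, coefficients) is returned for recovery tests.

# deterministic config checksum: polynomial rolling hash mod 2^31 - 1
config_checksum <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Superellipsoid analysis mask emulating a brain parenchyma footprint
#'
#' @param grid a `volume_grid`.
#' @param semi_factor semi-axes as a fraction of the half-extent per axis.
#' @param exponent superellipsoid exponent (2 = ellipsoid; larger = boxier).
#' @return logical array over the grid.
#' @export
synth_brain_mask <- function(grid, semi_factor = 0.88, exponent = 4) {
  co <- grid_coordinates(grid)
  half <- (grid$shape - 1) / 2 * grid$voxel_size_mm
  semi <- pmax(half * semi_factor, grid$voxel_size_mm)
  r <- (abs(co[, 1]) / semi[1])^exponent + (abs(co[, 2]) / semi[2])^exponent +
    (abs(co[, 3]) / semi[3])^exponent
  array(r <= 1, dim = grid$shape)
}

#' Default hub layout of the synthetic tremor-treatment template
#'
#' Bilateral positive hubs in sensorimotor cortex and cerebellum, negative
#' hubs in frontal and occipital cortex.  Coordinates are in world mm on the
#' default 24 x 28 x 24 grid at 4 mm.
#'
#' @param lateralized if TRUE, only the left-hemisphere cortical hubs are
#'   kept (cerebellar hubs retained bilaterally), mimicking a published
#'   left-lateralized template.
#' @return a data frame with columns x, y, z, radius_mm, sign, weight.
#' @export
tremor_network_hubs <- function(lateralized = FALSE) {
  h <- data.frame(
    x = c(-30, 30, -14, 14, -20, 20, -18, 18),
    y = c(-22, -22, -44, -44, 36, 36, -48, -48),
    z = c(34, 34, -30, -30, 18, 18, 4, 4),
    radius_mm = c(12, 12, 10, 10, 10, 10, 9, 9),
    sign = c(1, 1, 1, 1, -1, -1, -1, -1),
    weight = c(1, 1, 0.8, 0.8, 0.6, 0.6, 0.6, 0.6),
    region = c("M1_L", "M1_R", "cereb_L", "cereb_R",
               "frontal_L", "frontal_R", "occip_L", "occip_R"),
    stringsAsFactors = FALSE)
  if (lateralized) h <- h[h$x < 0 | grepl("cereb", h$region), ]
  h
}

#' Build a smooth hub-based template network map
#'
#' Sum of signed spherical indicator hubs, Gaussian-smoothed.  Deterministic.
#'
#' @param grid a `volume_grid`.
#' @param hubs data frame with columns x, y, z (world mm), radius_mm, sign
#'   (+1/-1), weight (> 0).
#' @param smooth_fwhm_mm smoothing kernel FWHM in mm.
#' @param mask optional logical array; defaults to all-true.
#' @return a `brain_map`.
#' @export
make_template_network <- function(grid, hubs = tremor_network_hubs(),
                                  smooth_fwhm_mm = 8, mask = NULL) {
  co <- grid_coordinates(grid)
  lo <- grid$origin_mm - grid$voxel_size_mm / 2
  hi <- grid$origin_mm + (grid$shape - 0.5) * grid$voxel_size_mm
  arr <- numeric(nrow(co))
  for (i in seq_len(nrow(hubs))) {
    ctr <- c(hubs$x[i], hubs$y[i], hubs$z[i])
    if (any(ctr < lo) || any(ctr > hi))
      tn_stop(sprintf("hub %d centre (%g, %g, %g) lies outside the grid",
                      i, ctr[1], ctr[2], ctr[3]), "tremornet_placement_error")
    d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
    arr <- arr + hubs$sign[i] * hubs$weight[i] * (d2 <= hubs$radius_mm[i]^2)
  }
  m <- brain_map(grid, array(arr, dim = grid$shape), mask)
  if (smooth_fwhm_mm > 0) m <- gaussian_smooth(m, smooth_fwhm_mm) else m
}

# smooth unit-variance Gaussian random field on the grid (in-mask sd = sd)
smooth_noise_field <- function(grid, mask, fwhm_mm, sd) {
  if (sd <= 0) return(brain_map(grid, array(0, dim = grid$shape), mask))
  m <- brain_map(grid, array(stats::rnorm(prod(grid$shape)), dim = grid$shape), mask)
  if (fwhm_mm > 0) m <- gaussian_smooth(m, fwhm_mm)
  v <- map_values(m)
  s <- stats::sd(v)
  map_with_values(m, (v - 0) / s * sd)
}

sphere_mask <- function(grid, center, radius) {
  co <- grid_coordinates(grid)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 + (co[, 3] - center[3])^2
  array(d2 <= radius^2, dim = grid$shape)
}

#' Generator settings for a synthetic DBS FDG-PET cohort
#'
#' Defaults emulate the study conditions this package analyses: 14 patients,
#' a 24 x 28 x 24 grid at 4 mm, intensity-normalized uptake around 1, an 8 mm
#' noise correlation length, an amplitude-driven local effect at a thalamic
#' stimulation locus, and a network gain coupled to relative tremor
#' improvement (improvement% = beta0 + beta1 * g + noise).
#'
#' @param n number of patients.
#' @param shape,voxel_mm grid geometry (grid centred on world 0).
#' @param hubs template hub layout (see [tremor_network_hubs()]).
#' @param template_fwhm_mm template smoothing FWHM (mm).
#' @param c_T network effect scale; On-Off gains `g * c_T` on the template.
#' @param c_L local effect scale per mA of stimulation amplitude.
#' @param stim_center_mm right-hemisphere stimulation locus (mirrored left).
#' @param local_radius_mm radius of the local-effect kernel spheres.
#' @param vta_radius_base_mm,vta_radius_per_mA VTA sphere radius
#'   `base + per_mA * amplitude`.
#' @param vta_jitter_sd_mm per-patient jitter SD of the VTA/local centre.
#' @param noise_fwhm_mm,noise_sd smooth imaging-noise field FWHM and in-mask SD
#'   (per condition map; 0 disables noise).
#' @param s_sd SD of the tremor-severity factor s.
#' @param g_mean,g_sd distribution of the network gain g.
#' @param amplitude_range_mA uniform range of stimulation amplitude.
#' @param pulse_widths_us,frequencies_Hz discrete stimulation-setting pools.
#' @param alpha0,alpha1,trs_noise_sd severity model: trs_off = alpha0 +
#'   alpha1 * s + noise (clipped at 0).
#' @param beta0,beta1,clinical_noise_sd improvement model (percent).
#' @param conn_noise_sd smooth-noise SD added to the template to form each
#'   patient's normative connectivity map.
#' @param baseline constant baseline uptake.
#' @param mask_semi_factor,mask_exponent analysis-mask geometry.
#' @param round_trs round tremor scores to integers (off by default; the
#'   downstream statistics are on continuous scores).
#' @return a list of class `tn_cohort_config`.
#' @export
cohort_config <- function(n = 14, shape = c(24, 28, 24), voxel_mm = 4,
                          hubs = tremor_network_hubs(), template_fwhm_mm = 8,
                          c_T = 0.05, c_L = 0.03,
                          stim_center_mm = c(12, -18, 2), local_radius_mm = 6,
                          vta_radius_base_mm = 2, vta_radius_per_mA = 0.8,
                          vta_jitter_sd_mm = 1.5,
                          noise_fwhm_mm = 8, noise_sd = 0.03,
                          s_sd = 1, g_mean = 1.5, g_sd = 1,
                          amplitude_range_mA = c(1.5, 4.5),
                          pulse_widths_us = c(60, 90, 120),
                          frequencies_Hz = c(130, 145, 160, 180),
                          alpha0 = 15, alpha1 = 3, trs_noise_sd = 1.5,
                          beta0 = 60, beta1 = 10, clinical_noise_sd = 8,
                          conn_noise_sd = 0.10, baseline = 1,
                          mask_semi_factor = 0.88, mask_exponent = 4,
                          round_trs = FALSE) {
  cfg <- as.list(environment())
  if (!is.numeric(n) || n < 1) tn_stop("'n' must be a positive count", "tremornet_config_error")
  if (noise_sd < 0 || trs_noise_sd < 0 || clinical_noise_sd < 0 || conn_noise_sd < 0)
    tn_stop("noise SDs must be >= 0", "tremornet_config_error")
  cfg$n <- as.integer(n)
  class(cfg) <- "tn_cohort_config"
  cfg
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generative model, per patient i (all maps on the analysis mask):
#' `off_i = baseline + s_i * T + e_off`;
#' `on_i = off_i + a_i * c_L * L + g_i * c_T * T + e_on`;
#' `trs_off = alpha0 + alpha1 * s_i + eta` (clipped at 0);
#' `improvement% = beta0 + beta1 * g_i + eta'`;
#' `trs_on = trs_off * (1 - improvement/100)` clipped at 0.
#' T is the hub template, L the local stimulation kernel, e and eta Gaussian.
#' All randomness is drawn from a per-patient substream with seed
#' `seed + patient_index` (rule recorded in the ground truth).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with elements `cohort` (class `tn_cohort`) and `truth`
#'   (class `tn_ground_truth`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "tn_cohort_config"))
  grid <- volume_grid(config$shape, config$voxel_mm)
  mask <- synth_brain_mask(grid, config$mask_semi_factor, config$mask_exponent)
  template <- make_template_network(grid, config$hubs, config$template_fwhm_mm, mask = mask)

  stim_r <- config$stim_center_mm
  stim_l <- stim_r * c(-1, 1, 1)
  local_ind <- sphere_mask(grid, stim_r, config$local_radius_mm) |
    sphere_mask(grid, stim_l, config$local_radius_mm)
  local_kernel <- brain_map(grid, array(as.numeric(local_ind), dim = grid$shape), mask)
  if (config$template_fwhm_mm > 0)
    local_kernel <- gaussian_smooth(local_kernel, config$template_fwhm_mm)

  Tv <- template$data; Lv <- local_kernel$data
  patients <- vector("list", config$n)
  pt <- data.frame(id = sprintf("P%02d", seq_len(config$n)), s = NA_real_, g = NA_real_,
                   amplitude = NA_real_, pulse_width = NA_real_, frequency = NA_real_,
                   improvement_planted = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(config$n)) {
    set.seed(seed + i)
    s_i <- stats::rnorm(1, 0, config$s_sd)
    g_i <- stats::rnorm(1, config$g_mean, config$g_sd)
    a_i <- stats::runif(1, config$amplitude_range_mA[1], config$amplitude_range_mA[2])
    pw_i <- sample(config$pulse_widths_us, 1)
    fr_i <- sample(config$frequencies_Hz, 1)
    jit <- if (config$vta_jitter_sd_mm > 0) stats::rnorm(3, 0, config$vta_jitter_sd_mm) else c(0, 0, 0)

    e_off <- smooth_noise_field(grid, mask, config$noise_fwhm_mm, config$noise_sd)
    e_on <- smooth_noise_field(grid, mask, config$noise_fwhm_mm, config$noise_sd)
    off_arr <- config$baseline + s_i * Tv + e_off$data
    on_arr <- off_arr + a_i * config$c_L * Lv + g_i * config$c_T * Tv + e_on$data
    off_map <- brain_map(grid, off_arr, mask)
    on_map <- brain_map(grid, on_arr, mask)

    trs_off <- max(0, config$alpha0 + config$alpha1 * s_i +
                     stats::rnorm(1, 0, config$trs_noise_sd))
    imp <- config$beta0 + config$beta1 * g_i + stats::rnorm(1, 0, config$clinical_noise_sd)
    trs_on <- max(0, trs_off * (1 - imp / 100))
    if (config$round_trs) { trs_off <- round(trs_off); trs_on <- round(trs_on) }

    r_vta <- config$vta_radius_base_mm + config$vta_radius_per_mA * a_i
    ctr_r <- stim_r + jit
    ctr_l <- ctr_r * c(-1, 1, 1)
    vta <- sphere_mask(grid, ctr_r, r_vta) | sphere_mask(grid, ctr_l, r_vta)

    conn_noise <- smooth_noise_field(grid, mask, config$noise_fwhm_mm, config$conn_noise_sd)
    conn_map <- brain_map(grid, Tv + conn_noise$data, mask)

    patients[[i]] <- list(id = pt$id[i], off_map = off_map, on_map = on_map,
                          trs_off = trs_off, trs_on = trs_on,
                          amplitude = a_i, pulse_width = pw_i, frequency = fr_i,
                          vta_mask = vta, conn_map = conn_map)
    pt[i, c("s", "g", "amplitude", "pulse_width", "frequency", "improvement_planted")] <-
      c(s_i, g_i, a_i, pw_i, fr_i, imp)
  }
  cohort <- structure(list(patients = patients, grid = grid, analysis_mask = mask),
                      class = "tn_cohort")
  cfg <- unclass(config)
  cfg_str <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  truth <- structure(list(
    template_network = template, local_kernel = local_kernel,
    patients = tibble::as_tibble(pt),
    coefficients = list(alpha0 = config$alpha0, alpha1 = config$alpha1,
                        beta0 = config$beta0, beta1 = config$beta1,
                        c_T = config$c_T, c_L = config$c_L),
    noise = list(noise_fwhm_mm = config$noise_fwhm_mm, noise_sd = config$noise_sd,
                 trs_noise_sd = config$trs_noise_sd,
                 clinical_noise_sd = config$clinical_noise_sd,
                 conn_noise_sd = config$conn_noise_sd),
    seed = seed, split_rule = "patient_seed = seed + patient_index",
    config = config, config_hash = config_checksum(cfg_str)), class = "tn_ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Number of patients in a cohort
#' @param cohort a `tn_cohort`.
#' @return integer count.
#' @export
cohort_size <- function(cohort) length(cohort$patients)

#' Clinical table of a cohort
#' @param cohort a `tn_cohort`.
#' @return tibble with columns id, trs_off, trs_on, amplitude_mA,
#'   pulse_width_us, frequency_Hz.
#' @export
clinical_table <- function(cohort) {
  tibble::tibble(
    id = vapply(cohort$patients, `[[`, character(1), "id"),
    trs_off = vapply(cohort$patients, `[[`, numeric(1), "trs_off"),
    trs_on = vapply(cohort$patients, `[[`, numeric(1), "trs_on"),
    amplitude_mA = vapply(cohort$patients, `[[`, numeric(1), "amplitude"),
    pulse_width_us = vapply(cohort$patients, `[[`, numeric(1), "pulse_width"),
    frequency_Hz = vapply(cohort$patients, `[[`, numeric(1), "frequency"))
}

#' Write a cohort (and its ground truth) to a directory
#'
#' Layout: `clinical.tsv`, `ground_truth.json`, `analysis_mask.nii.gz`,
#' `template_network.nii.gz`, `local_kernel.nii.gz`, and per patient
#' `patients/<id>_{off,on,conn}.nii.gz` plus `<id>_vta.nii.gz` (uint8).
#'
#' @param cohort a `tn_cohort`.
#' @param truth the matching `tn_ground_truth` (optional).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, truth = NULL, dir) {
  for (p in cohort$patients)
    if (is.null(p$off_map) || is.null(p$on_map) || is.null(p$vta_mask) || is.null(p$conn_map))
      tn_stop("partial cohorts cannot be written", "tremornet_cohort_error")
  dir.create(file.path(dir, "patients"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(clinical_table(cohort)),
                     file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_mask(brain_map(cohort$grid, array(1, cohort$grid$shape), cohort$analysis_mask),
             file.path(dir, "analysis_mask.nii.gz"))
  for (p in cohort$patients) {
    write_volume(p$off_map, file.path(dir, "patients", paste0(p$id, "_off.nii.gz")))
    write_volume(p$on_map, file.path(dir, "patients", paste0(p$id, "_on.nii.gz")))
    write_volume(p$conn_map, file.path(dir, "patients", paste0(p$id, "_conn.nii.gz")))
    write_mask(p$vta_mask, file.path(dir, "patients", paste0(p$id, "_vta.nii.gz")),
               grid = cohort$grid)
  }
  if (!is.null(truth)) {
    write_volume(truth$template_network, file.path(dir, "template_network.nii.gz"))
    write_volume(truth$local_kernel, file.path(dir, "local_kernel.nii.gz"))
    rec <- truth[c("patients", "coefficients", "noise", "seed", "split_rule", "config_hash")]
    rec$config <- unclass(truth$config)
    rec$config$hubs <- NULL
    jsonlite::write_json(rec, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory path.
#' @return list with `cohort` (class `tn_cohort`) and `truth` (NULL when no
#'   ground-truth record is present; volumes and tables restored otherwise).
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.delim(file.path(dir, "clinical.tsv"), sep = "\t",
                            stringsAsFactors = FALSE)
  amask_map <- read_volume(file.path(dir, "analysis_mask.nii.gz"), mask = "nonzero")
  grid <- amask_map$grid
  mask <- amask_map$mask
  patients <- lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$id[i]
    pth <- function(sfx) file.path(dir, "patients", paste0(id, "_", sfx, ".nii.gz"))
    list(id = id,
         off_map = read_volume(pth("off"), mask = mask),
         on_map = read_volume(pth("on"), mask = mask),
         trs_off = clin$trs_off[i], trs_on = clin$trs_on[i],
         amplitude = clin$amplitude_mA[i], pulse_width = clin$pulse_width_us[i],
         frequency = clin$frequency_Hz[i],
         vta_mask = read_volume(pth("vta"))$data > 0.5,
         conn_map = read_volume(pth("conn"), mask = mask))
  })
  cohort <- structure(list(patients = patients, grid = grid, analysis_mask = mask),
                      class = "tn_cohort")
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    rec <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    rec$patients <- tibble::as_tibble(rec$patients)
    rec$template_network <- read_volume(file.path(dir, "template_network.nii.gz"), mask = mask)
    rec$local_kernel <- read_volume(file.path(dir, "local_kernel.nii.gz"), mask = mask)
    truth <- structure(rec, class = "tn_ground_truth")
  }
  list(cohort = cohort, truth = truth)
}
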