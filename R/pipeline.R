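# End-to-end orchestration: preprocessing, clinical stats, voxel-wise
# stimulation-effect and severity maps, surrogate similarity tests,
# alignment and outcome regression, the local VTA-ROI analysis, the
# connectivity GLM, and the covariance-pattern cross-check, with one run
# seed deriving every stage seed and a JSON summary recording settings,
# seeds, and method deviations.

#' Pipeline settings
#'
#' @param stages character vector of stages to run, any of "clinical",
#'   "stim_effect", "severity", "similarity", "alignment", "local",
#'   "connglm", "ortcva".
#' @param n_perm permutations for voxel-wise tests.
#' @param n_surr surrogates for similarity tests.
#' @param similarity_resample_mm voxel size the maps are block-resampled to
#'   for the dense surrogate eigenbasis (the similarity stage only).
#' @param metric alignment metric ("spearman" or "product_sum").
#' @param alpha significance level for clinical calls.
#' @param cluster_forming_p,cluster_n_perm cluster correction settings.
#' @param voxel_cap dense-basis voxel cap.
#' @return list of class `tn_pipeline_config`.
#' @export
pipeline_config <- function(stages = c("clinical", "stim_effect", "severity",
                                       "similarity", "alignment", "local",
                                       "connglm", "ortcva"),
                            n_perm = 2000, n_surr = 1000,
                            similarity_resample_mm = 8,
                            metric = "spearman", alpha = 0.05,
                            cluster_forming_p = 0.001, cluster_n_perm = 200,
                            voxel_cap = 10000) {
  known <- c("clinical", "stim_effect", "severity", "similarity", "alignment",
             "local", "connglm", "ortcva")
  if (length(stages) == 0 || !all(stages %in% known))
    tn_stop("no valid stages selected", "tremornet_config_error")
  cfg <- as.list(environment())
  cfg$known <- NULL
  structure(cfg, class = "tn_pipeline_config")
}

sim_pair <- function(map_a, map_b, n_surr, seed, support, voxel_cap, resample_mm = NULL) {
  if (!is.null(resample_mm)) {
    map_a <- resample(map_a, resample_mm)
    map_b <- resample(map_b, resample_mm)
  }
  list(permute_a = similarity_test(map_a, map_b, n_surr = n_surr, seed = seed,
                                   permuted_side = "a", support = support,
                                   voxel_cap = voxel_cap),
       permute_b = similarity_test(map_a, map_b, n_surr = n_surr, seed = seed + 1,
                                   permuted_side = "b", support = support,
                                   voxel_cap = voxel_cap))
}

sim_summary <- function(sp) list(rho = sp$permute_a$rho_obs,
                                 p_permute_a = sp$permute_a$p,
                                 p_permute_b = sp$permute_b$p)

#' Run the full analysis pipeline on a cohort
#'
#' Executes the selected stages in the fixed order clinical -> difference
#' maps -> one-sample permutation t -> severity regressions -> similarity
#' tests -> alignment + outcome regression -> VTA-ROI local analysis ->
#' connectivity GLM with cluster correction -> covariance-pattern analysis.
#' Each stochastic stage receives a seed derived from the run seed (recorded
#' in the summary).
#'
#' @param cohort a `tn_cohort`.
#' @param template a `brain_map` tremor-treatment template on the cohort
#'   grid (bilateral, or prepared via [prepare_template()]).
#' @param config a [pipeline_config()].
#' @param seed run seed.
#' @param output_dir optional directory; when given, statistical maps
#'   (NIfTI), tables (TSV) and the JSON summary are written there.
#' @return list of class `tn_pipeline_result` with one element per stage
#'   plus `summary` (the JSON-serializable record).
#' @export
run_pipeline <- function(cohort, template, config = pipeline_config(), seed = 1,
                         output_dir = NULL) {
  stopifnot(inherits(config, "tn_pipeline_config"))
  st <- config$stages
  res <- list()
  seeds <- list(stim_effect = seed + 101, severity = seed + 202,
                improvement_reg = seed + 303, similarity = seed + 404,
                connglm = seed + 505, ortcva = seed + 606)
  clin <- clinical_table(cohort)
  deltas <- diff_maps(cohort)
  improvement <- relative_improvement(clin$trs_off, clin$trs_on)

  if ("clinical" %in% st) {
    pt <- paired_ttest(clin$trs_off, clin$trs_on)
    res$clinical <- list(
      paired = pt,
      mean_relative_improvement_pct = mean(improvement, na.rm = TRUE),
      improvement_range_pct = range(improvement, na.rm = TRUE),
      group_mean_ratio_improvement_pct =
        relative_improvement(mean(clin$trs_off), mean(clin$trs_on)))
  }
  if ("stim_effect" %in% st)
    res$stim_effect <- one_sample_perm_t(deltas, n_perm = config$n_perm,
                                         seed = seeds$stim_effect)
  if ("severity" %in% st) {
    off_maps <- lapply(cohort$patients, `[[`, "off_map")
    on_maps <- lapply(cohort$patients, `[[`, "on_map")
    res$severity_off <- voxelwise_regression(off_maps, clin$trs_off,
                                             n_perm = config$n_perm,
                                             seed = seeds$severity)
    res$severity_on_residual <- voxelwise_regression(on_maps, clin$trs_on,
                                                     n_perm = config$n_perm,
                                                     seed = seeds$severity + 1)
    res$improvement_reg <- voxelwise_regression(deltas, improvement,
                                                n_perm = config$n_perm,
                                                seed = seeds$improvement_reg)
  }
  if ("similarity" %in% st) {
    need <- c("stim_effect", "severity")
    if (!all(need %in% st))
      tn_stop("similarity stage requires stim_effect and severity stages",
              "tremornet_config_error")
    rs <- config$similarity_resample_mm
    s <- seeds$similarity
    res$similarity <- list(
      stim_effect_vs_template = sim_pair(res$stim_effect$stat, template,
                                         config$n_surr, s, "nonzero_b",
                                         config$voxel_cap, rs),
      expression_off_vs_template = sim_pair(res$severity_off$stat, template,
                                            config$n_surr, s + 10, "nonzero_b",
                                            config$voxel_cap, rs),
      expression_on_vs_expression_off = sim_pair(res$severity_on_residual$stat,
                                                 res$severity_off$stat,
                                                 config$n_surr, s + 20,
                                                 "intersection_mask",
                                                 config$voxel_cap, rs),
      expression_on_vs_stim_effect = sim_pair(res$severity_on_residual$stat,
                                              res$stim_effect$stat,
                                              config$n_surr, s + 30,
                                              "intersection_mask",
                                              config$voxel_cap, rs),
      expression_off_vs_stim_effect = sim_pair(res$severity_off$stat,
                                               res$stim_effect$stat,
                                               config$n_surr, s + 40,
                                               "intersection_mask",
                                               config$voxel_cap, rs))
  }
  if ("alignment" %in% st) {
    amp <- clin$amplitude_mA
    align <- cohort_alignment(cohort, template, metric = config$metric)
    res$alignment <- list(
      scores = align,
      outcome = outcome_regression(improvement, align$z,
                                   covariates = data.frame(amplitude = amp)),
      screening = screen_confounds(align$z,
                                   data.frame(amplitude = amp,
                                              pulse_width = clin$pulse_width_us,
                                              frequency = clin$frequency_Hz),
                                   alpha = config$alpha))
  }
  if ("local" %in% st) {
    roi <- vta_overlap_roi(cohort, min_overlap = 3)
    amp_fit <- stats::lm(roi$uptake$z ~ clin$amplitude_mA)
    sm <- summary(amp_fit)
    res$local <- list(
      roi_n_voxels = roi$n_voxels, uptake = roi$uptake,
      amplitude_r_squared = sm$r.squared,
      amplitude_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                              lower.tail = FALSE),
      outcome = outcome_regression(improvement, roi$uptake$z,
                                   covariates = data.frame(amplitude = clin$amplitude_mA)))
  }
  if ("connglm" %in% st) {
    conn_maps <- lapply(cohort$patients, `[[`, "conn_map")
    fit <- connectivity_glm(deltas, conn_maps, clin$amplitude_mA)
    clus <- list()
    for (pred in c("pos", "neg", "amplitude")) {
      if (pred == "amplitude" && !fit$use_amplitude) next
      if (is.null(fit$t_maps[[pred]])) next
      clus[[pred]] <- cluster_correct(fit, pred,
                                      cluster_forming_p = config$cluster_forming_p,
                                      n_perm = config$cluster_n_perm,
                                      seed = seeds$connglm)
    }
    res$connglm <- list(fit = fit, clusters = clus)
  }
  if ("ortcva" %in% st) {
    on_maps <- lapply(cohort$patients, `[[`, "on_map")
    off_maps <- lapply(cohort$patients, `[[`, "off_map")
    res$ortcva <- ortcva_fit(on_maps, off_maps, seed = seeds$ortcva)
    if ("stim_effect" %in% st) {
      rs <- config$similarity_resample_mm
      res$ortcva_vs_tmap <- sim_pair(res$ortcva$pattern, res$stim_effect$stat,
                                     config$n_surr, seeds$ortcva + 1,
                                     "intersection_mask", config$voxel_cap, rs)
    }
  }

  summary_rec <- list(
    schema_version = "1.0",
    seed = seed, stage_seeds = seeds,
    settings = unclass(config),
    n_patients = cohort_size(cohort),
    deviations = c("rigid reflection mirroring (not nonlinear warp)",
                   "permutation max-cluster correction (not random-field theory)",
                   "simplified ordinal-trends covariance analysis"),
    results = list())
  if (!is.null(res$clinical))
    summary_rec$results$clinical <- list(
      p_paired = res$clinical$paired$p, t = res$clinical$paired$t,
      mean_off = res$clinical$paired$mean_off, mean_on = res$clinical$paired$mean_on,
      mean_relative_improvement_pct = res$clinical$mean_relative_improvement_pct)
  if (!is.null(res$stim_effect))
    summary_rec$results$stim_effect <- list(
      max_abs_t = max(abs(map_values(res$stim_effect$stat))),
      n_sig_fwe05 = sum(map_values(res$stim_effect$p_fwe) <= 0.05))
  if (!is.null(res$similarity))
    summary_rec$results$similarity <- lapply(res$similarity, sim_summary)
  if (!is.null(res$alignment))
    summary_rec$results$alignment <- list(
      r_squared_with_amplitude = res$alignment$outcome$r_squared,
      p_with_amplitude = res$alignment$outcome$p_model,
      r_squared_alignment_only = res$alignment$outcome$base_model$r_squared,
      p_alignment_only = res$alignment$outcome$base_model$p_model)
  if (!is.null(res$local))
    summary_rec$results$local <- list(
      amplitude_r_squared = res$local$amplitude_r_squared,
      outcome_r_squared = res$local$outcome$r_squared)
  if (!is.null(res$connglm))
    summary_rec$results$connglm <- lapply(res$connglm$clusters, function(cl)
      list(n_clusters = nrow(cl$clusters),
           n_significant = sum(cl$clusters$p <= 0.05)))
  if (!is.null(res$ortcva)) {
    summary_rec$results$ortcva <- list(
      ordinal_violations = res$ortcva$ordinal_violations,
      paired_t = res$ortcva$paired_t)
    if (!is.null(res$ortcva_vs_tmap))
      summary_rec$results$ortcva_vs_tmap <- sim_summary(res$ortcva_vs_tmap)
  }
  res$summary <- summary_rec

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$stim_effect)) {
      write_volume(res$stim_effect$stat, file.path(output_dir, "stim_effect_t.nii.gz"))
      write_volume(res$stim_effect$p_fwe, file.path(output_dir, "stim_effect_pfwe.nii.gz"))
      utils::write.table(as.data.frame(statmap_table(res$stim_effect)),
                         file.path(output_dir, "stim_effect_suprathreshold.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$alignment))
      utils::write.table(as.data.frame(res$alignment$scores),
                         file.path(output_dir, "alignment_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$ortcva)) {
      write_volume(res$ortcva$pattern, file.path(output_dir, "ortcva_pattern.nii.gz"))
      write_volume(res$ortcva$bootstrap_z, file.path(output_dir, "ortcva_bootstrap_z.nii.gz"))
      utils::write.table(as.data.frame(res$ortcva$expression),
                         file.path(output_dir, "ortcva_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary_rec, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(res, class = "tn_pipeline_result")
}
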