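# Clinical statistics: the paired condition comparison, relative tremor
# improvement, stimulation-parameter confound screening, the
# amplitude-controlled outcome regression, and the cohort-level VTA-overlap
# stimulation-site ROI.

#' Paired t-test between Stim-Off and Stim-On scores
#'
#' Classical paired t on d = off - on (positive mean difference =
#' improvement); the On-Off signed change is also reported.
#'
#' @param off,on numeric vectors of equal length (n >= 2).
#' @param tail `"two_sided"`, `"greater"` or `"less"` (for the mean of d).
#' @return object of class `tn_paired_ttest` with fields mean_off, mean_on,
#'   mean_diff, sem_diff, change_on_minus_off, t, df, p, n, tail.
#' @export
paired_ttest <- function(off, on, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(off)
  if (length(on) != n || n < 2)
    tn_stop("'off' and 'on' must have equal length n >= 2", "tremornet_arg_error")
  d <- off - on
  sdd <- stats::sd(d)
  if (sdd == 0)
    tn_stop("zero variance of paired differences; t is degenerate",
            "tremornet_degenerate_data")
  sem <- sdd / sqrt(n)
  t <- mean(d) / sem
  df <- n - 1L
  p <- switch(tail,
              two_sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  structure(list(mean_off = mean(off), mean_on = mean(on), mean_diff = mean(d),
                 sem_diff = sem, change_on_minus_off = -mean(d), t = t, df = df,
                 p = p, n = n, tail = tail),
            class = "tn_paired_ttest")
}

#' @export
print.tn_paired_ttest <- function(x, ...) {
  cat(sprintf("<tn_paired_ttest> Off %.2f, On %.2f (mean +/- SEM change %.2f +/- %.2f); t(%d) = %.3f, p = %.3g (%s)\n",
              x$mean_off, x$mean_on, x$change_on_minus_off, x$sem_diff, x$df, x$t, x$p, x$tail))
  invisible(x)
}

#' Relative tremor improvement in percent
#'
#' 100 * (off - on) / off per patient.  Negative values (worsening) are
#' allowed; patients with off = 0 have undefined improvement and are
#' returned as NA with a warning.
#'
#' @param off,on numeric vectors (off severity > 0 for a defined value).
#' @return numeric vector of percentages.
#' @export
relative_improvement <- function(off, on) {
  stopifnot(length(off) == length(on))
  bad <- off == 0
  out <- ifelse(bad, NA_real_, 100 * (off - on) / off)
  if (any(bad))
    warning(warningCondition(
      sprintf("improvement undefined for %d patient(s) with off = 0; excluded as NA",
              sum(bad)),
      class = "tremornet_undefined_improvement"))
  out
}

#' Screen stimulation parameters as confounds of a response
#'
#' Per parameter: Pearson r, R-squared and p against the response; variance
#' inflation factors from the all-parameter model; and partial t/p from the
#' joint multiple regression.  Parameters are marked significant independent
#' predictors when their joint-model p is below `alpha`.
#'
#' @param response numeric vector (e.g. z-scored ROI FDG uptake change).
#' @param params data frame of stimulation parameters (columns e.g.
#'   amplitude, pulse_width, frequency).
#' @param alpha significance level for the independence call.
#' @return tibble with one row per parameter: r, r_squared, p_univariate,
#'   vif, estimate_joint, t_joint, p_joint, significant_independent.
#' @export
screen_confounds <- function(response, params, alpha = 0.05) {
  params <- as.data.frame(params)
  n <- length(response)
  if (nrow(params) != n) tn_stop("response/params length mismatch", "tremornet_arg_error")
  if (n < 4) tn_stop("need n >= 4 for screening", "tremornet_insufficient_data")
  const <- vapply(params, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("constant parameter column(s) excluded: %s",
                    paste(names(params)[const], collapse = ", ")))
    params <- params[, !const, drop = FALSE]
  }
  k <- ncol(params)
  if (k == 0) tn_stop("no non-constant parameters to screen", "tremornet_arg_error")
  if (n - k - 1 < 1)
    tn_stop("insufficient residual df for the joint model", "tremornet_insufficient_df")
  uni <- lapply(params, function(v) {
    ct <- stats::cor.test(response, v)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  vif <- vapply(seq_len(k), function(j) {
    if (k == 1) return(1)
    r2 <- summary(stats::lm(params[[j]] ~ ., data = params[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  joint <- stats::lm(response ~ ., data = params)
  cf <- summary(joint)$coefficients
  rows <- match(names(params), rownames(cf))
  est <- ifelse(is.na(rows), NA_real_, cf[rows, 1])
  tj <- ifelse(is.na(rows), NA_real_, cf[rows, 3])
  pj <- ifelse(is.na(rows), NA_real_, cf[rows, 4])
  rr <- unname(vapply(uni, `[[`, numeric(1), "r"))
  tibble::tibble(
    parameter = names(params),
    r = rr, r_squared = rr^2,
    p_univariate = unname(vapply(uni, `[[`, numeric(1), "p")),
    vif = vif, estimate_joint = unname(est), t_joint = unname(tj),
    p_joint = unname(pj),
    significant_independent = unname(!is.na(pj) & pj < alpha))
}

#' Outcome regression of improvement on network alignment
#'
#' OLS of relative improvement on the z-scored alignment score, with and
#' without covariates (e.g. stimulation amplitude).  The covariate-free
#' model is always reported alongside, matching the paired reporting of the
#' unadjusted and amplitude-adjusted associations.
#'
#' @param improvement percent improvement per patient.
#' @param alignment_z z-scored alignment score per patient.
#' @param covariates optional data frame of covariates.
#' @return object of class `tn_outcome_regression` with fields `r_squared`,
#'   `p_model` (model F-test), `coefficients` (tibble), `alignment`
#'   (estimate/t/p of the alignment term), `base_model` (covariate-free
#'   r_squared, p_model, alignment p), `n`, `predictors`.
#' @export
outcome_regression <- function(improvement, alignment_z, covariates = NULL) {
  keep <- is.finite(improvement) & is.finite(alignment_z)
  df <- data.frame(improvement = improvement, alignment_z = alignment_z)[keep, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    df <- cbind(df, covariates)
  }
  n <- nrow(df)
  k <- ncol(df) - 1L
  if (n < k + 2) tn_stop("need n >= predictors + 2", "tremornet_insufficient_data")
  fit_one <- function(dat) {
    fit <- stats::lm(improvement ~ ., data = dat)
    if (fit$rank < ncol(dat))
      tn_stop("rank-deficient design", "tremornet_design_error")
    # exact fits are a designed use case (noise-free identity checks)
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
    fp <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
    list(fit = fit, sm = sm, r_squared = sm$r.squared, p_model = unname(fp))
  }
  full <- fit_one(df)
  base <- fit_one(df[, c("improvement", "alignment_z")])
  cf <- full$sm$coefficients
  co <- tibble::tibble(term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
                       t = cf[, 3], p = cf[, 4])
  al <- as.list(co[co$term == "alignment_z", c("estimate", "t", "p")])
  bcf <- base$sm$coefficients
  structure(list(r_squared = full$r_squared, p_model = full$p_model,
                 coefficients = co,
                 alignment = al,
                 base_model = list(r_squared = base$r_squared, p_model = base$p_model,
                                   estimate = bcf["alignment_z", 1],
                                   p = bcf["alignment_z", 4]),
                 n = n, predictors = setdiff(names(df), "improvement")),
            class = "tn_outcome_regression")
}

#' @export
print.tn_outcome_regression <- function(x, ...) {
  cat(sprintf("<tn_outcome_regression> n = %d; full model R^2 = %.3f (p = %.3g); alignment beta = %.3f (p = %.3g)\n",
              x$n, x$r_squared, x$p_model, x$alignment$estimate, x$alignment$p))
  cat(sprintf("  covariate-free: R^2 = %.3f (p = %.3g)\n",
              x$base_model$r_squared, x$base_model$p_model))
  invisible(x)
}

#' Cohort-level VTA-overlap stimulation-site ROI
#'
#' Voxels covered by at least `min_overlap` patients' VTAs, plus the
#' per-patient mean FDG change (or Stim-On uptake) inside the ROI, z-scored
#' across the cohort.
#'
#' @param cohort a `tn_cohort`.
#' @param min_overlap minimum number of overlapping VTAs (default 3).
#' @param uptake `"delta"` (mean On-Off change; default) or `"on"`
#'   (mean Stim-On uptake).
#' @return list with `roi` (logical array), `n_voxels`, and `uptake`
#'   (tibble: id, mean_uptake, z).
#' @export
vta_overlap_roi <- function(cohort, min_overlap = 3, uptake = c("delta", "on")) {
  uptake <- match.arg(uptake)
  counts <- Reduce(`+`, lapply(cohort$patients, function(p) p$vta_mask * 1L))
  roi <- counts >= min_overlap & cohort$analysis_mask
  if (!any(roi))
    tn_stop(sprintf("no voxel reaches %d overlapping VTAs; lower min_overlap",
                    min_overlap), "tremornet_threshold_error")
  vals <- vapply(cohort$patients, function(p) {
    m <- if (uptake == "delta") p$on_map$data - p$off_map$data else p$on_map$data
    mean(m[roi])
  }, numeric(1))
  s <- stats::sd(vals)
  z <- if (s > 0) (vals - mean(vals)) / s else rep(NA_real_, length(vals))
  list(roi = roi, n_voxels = sum(roi),
       uptake = tibble::tibble(id = vapply(cohort$patients, `[[`, character(1), "id"),
                               mean_uptake = vals, z = z))
}
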