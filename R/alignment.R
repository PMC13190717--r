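# Per-patient network-alignment scores: the similarity between a patient's
# On-Off metabolic change map and the template tremor-treatment network,
# z-scored across the cohort.  This is the quantity whose association with
# relative tremor improvement carries the headline clinical model.

#' Alignment of a change map with a template network
#'
#' @param delta a `brain_map` (per-patient On-Off change map).
#' @param template a `brain_map` on the same grid.
#' @param metric `"spearman"` (rank correlation, average ranks for ties) or
#'   `"product_sum"` (unnormalized sum of voxel-wise products).
#' @param support `"nonzero_template"` (voxels where the template is exactly
#'   nonzero, intersected with both masks; no magnitude threshold) or
#'   `"intersection_mask"`.
#' @return scalar alignment score.
#' @export
alignment_score <- function(delta, template,
                            metric = c("spearman", "product_sum"),
                            support = c("nonzero_template", "intersection_mask")) {
  metric <- match.arg(metric)
  support <- match.arg(support)
  check_same_grid(delta, template)
  supp <- delta$mask & template$mask
  if (support == "nonzero_template") supp <- supp & template$data != 0
  if (sum(supp) < 10)
    tn_stop("alignment support has fewer than 10 voxels", "tremornet_support_error")
  dv <- delta$data[supp]; tv <- template$data[supp]
  if (metric == "spearman") {
    if (stats::sd(dv) == 0 || stats::sd(tv) == 0)
      tn_stop("constant values on the support; rank correlation undefined",
              "tremornet_constant_map")
    stats::cor(dv, tv, method = "spearman")
  } else {
    sum(dv * tv)
  }
}

#' Cohort-wide alignment scores, z-scored
#'
#' Raw per-patient scores via [alignment_score()] on each subtraction map,
#' standardized across the cohort with the sample (n - 1) SD.
#'
#' @param cohort a `tn_cohort`.
#' @param template a `brain_map` template network.
#' @param metric,support passed to [alignment_score()].
#' @param pet_transform optional function applied to each change map before
#'   scoring (e.g. the hemisphere-averaging directive of
#'   [prepare_template()]).
#' @return tibble with columns id, raw, z; attributes `metric` and
#'   `support_size`.
#' @export
cohort_alignment <- function(cohort, template,
                             metric = c("spearman", "product_sum"),
                             support = c("nonzero_template", "intersection_mask"),
                             pet_transform = NULL) {
  metric <- match.arg(metric)
  support <- match.arg(support)
  if (cohort_size(cohort) < 3) tn_stop("need >= 3 patients", "tremornet_insufficient_data")
  deltas <- diff_maps(cohort)
  if (!is.null(pet_transform)) deltas <- lapply(deltas, pet_transform)
  raw <- vapply(deltas, alignment_score, numeric(1),
                template = template, metric = metric, support = support)
  s <- stats::sd(raw)
  if (s == 0)
    tn_stop("zero cohort SD of alignment scores; z-scoring is degenerate",
            "tremornet_standardization_error")
  supp <- deltas[[1]]$mask & template$mask
  if (support == "nonzero_template") supp <- supp & template$data != 0
  out <- tibble::tibble(id = vapply(cohort$patients, `[[`, character(1), "id"),
                        raw = raw, z = (raw - mean(raw)) / s)
  attr(out, "metric") <- metric
  attr(out, "support_size") <- sum(supp)
  out
}

#' Reconcile a left-lateralized template with bilateral PET data
#'
#' Either the template is mirrored to a symmetric bilateral map (PET maps
#' untouched), or the template is kept and each PET change map is averaged
#' to the left hemisphere before scoring.
#'
#' @param template_left a left-lateralized `brain_map` template.
#' @param strategy `"mirror_template_bilateral"` or `"average_pet_to_left"`.
#' @return list with `template` (a `brain_map`) and `pet_transform` (a
#'   function applied to each change map; identity for the first strategy).
#' @export
prepare_template <- function(template_left,
                             strategy = c("mirror_template_bilateral", "average_pet_to_left")) {
  strategy <- match.arg(strategy)
  xs <- grid_coordinates(template_left$grid, axis = 1)
  left <- array(xs < 0, dim = template_left$grid$shape)
  if (!any(template_left$mask & left))
    tn_stop("template has no left-hemisphere voxels", "tremornet_input_error")
  if (strategy == "mirror_template_bilateral") {
    list(template = mirror(template_left, "left_to_right_bilateral"),
         pet_transform = identity, strategy = strategy)
  } else {
    list(template = template_left,
         pet_transform = function(m) mirror(m, "average_to_left"),
         strategy = strategy)
  }
}
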