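# Simplified ordinal-trends covariance pattern analysis: a multivariate
# spatial pattern, built in the subspace of the first principal components
# of the within-subject-centred condition maps, whose subject expression
# shifts as consistently as possible from Stim-Off to Stim-On.  The
# combining weights are the closed-form maximizer of the paired t statistic
# of projected On-Off differences in the retained component space; voxel
# stability is assessed by a subject-level bootstrap.

#' Fit a simplified ordinal-trends covariance pattern
#'
#' Algorithm: (1) stack the 2n condition maps and remove each subject's mean
#' map (within-subject centering); (2) PCA of the centred stack, keeping the
#' first `n_components` spatial components; (3) in component space, combine
#' the components with weights proportional to `solve(cov(d), mean(d))`
#' where d are the On-Off component coordinates (this maximizes the paired
#' t of projected differences over unit-norm weights); (4) map the weights
#' back to a unit-norm voxel pattern, sign-fixed so the mean projected
#' On-Off expression difference is positive; (5) count ordinal violations
#' (subjects whose On expression does not exceed their Off expression);
#' (6) bootstrap subjects with replacement, refit, sign-align, and form
#' per-voxel z = weight / bootstrap SD.
#'
#' A singular difference covariance falls back to a ridge (jitter
#' `1e-8 * trace`), flagged in the result.
#'
#' @param on_maps,off_maps paired lists of `brain_map`s (same subject order,
#'   common grid/mask; n >= n_components + 1).
#' @param n_components retained principal components (default 5).
#' @param n_boot bootstrap iterations (default 100).
#' @param seed integer seed for the bootstrap.
#' @return object of class `tn_ortcva`: `pattern` (unit-norm `brain_map`),
#'   `expression` (tibble: id index, condition, expression),
#'   `ordinal_violations`, `bootstrap_z` (`brain_map`), `weights`,
#'   `n_components`, `ridge_used`, `paired_t`.
#' @export
ortcva_fit <- function(on_maps, off_maps, n_components = 5, n_boot = 100, seed = 1) {
  n <- length(on_maps)
  if (length(off_maps) != n) tn_stop("unpaired condition maps", "tremornet_arg_error")
  if (n < n_components + 1)
    tn_stop("need n >= n_components + 1 subjects", "tremornet_insufficient_data")
  ON <- maps_to_matrix(on_maps)
  OFF <- maps_to_matrix(c(on_maps[1], off_maps))[-1, , drop = FALSE]
  ref <- on_maps[[1]]
  core <- function(ONm, OFFm) {
    subj_mean <- (ONm + OFFm) / 2
    M <- rbind(ONm - subj_mean, OFFm - subj_mean)     # within-subject centred
    sv <- svd(M, nu = 0, nv = n_components)
    Vc <- sv$v                                        # V x nc spatial components
    d <- (ONm - OFFm) %*% Vc                          # n x nc difference coords
    if (max(abs(d)) == 0)
      tn_stop("On equals Off for every subject; no ordinal direction exists",
              "tremornet_degenerate_fit")
    S <- stats::cov(d)
    md <- colMeans(d)
    w <- tryCatch(solve(S, md), error = function(e) NULL)
    ridge <- FALSE
    if (is.null(w) || any(!is.finite(w)) || kappa(S) > 1e12) {
      S2 <- S + diag(1e-8 * sum(diag(S)), nrow(S))
      w <- solve(S2, md)
      ridge <- TRUE
    }
    pat <- as.vector(Vc %*% w)
    pat <- pat / sqrt(sum(pat^2))
    if (mean((ONm - OFFm) %*% pat) < 0) pat <- -pat
    list(pattern = pat, w = w, ridge = ridge,
         singular_values = sv$d[seq_len(n_components)])
  }
  fit <- core(ON, OFF)
  pat <- fit$pattern
  expr_on <- as.vector(ON %*% pat)
  expr_off <- as.vector(OFF %*% pat)
  viol <- sum(expr_on <= expr_off)
  dexp <- expr_on - expr_off
  paired_t <- mean(dexp) / (stats::sd(dexp) / sqrt(n))

  set.seed(seed)
  boots <- matrix(NA_real_, length(pat), n_boot)
  ridge_boot <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    fb <- tryCatch(core(ON[idx, , drop = FALSE], OFF[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(fb)) next
    pb <- fb$pattern
    if (sum(pb * pat) < 0) pb <- -pb                  # sign-align to point estimate
    boots[, b] <- pb
    ridge_boot <- ridge_boot + fb$ridge
  }
  bsd <- apply(boots, 1, stats::sd, na.rm = TRUE)
  z <- pat / bsd
  z[!is.finite(z)] <- 0
  structure(list(
    pattern = map_with_values(ref, pat),
    expression = tibble::tibble(
      id = rep(seq_len(n), 2),
      condition = rep(c("on", "off"), each = n),
      expression = c(expr_on, expr_off)),
    ordinal_violations = viol,
    bootstrap_z = map_with_values(ref, z),
    component_weights = fit$w,
    n_components = n_components, n_boot = n_boot,
    ridge_used = fit$ridge, ridge_boot = ridge_boot,
    singular_values = fit$singular_values,
    paired_t = paired_t,
    deviation = "simplified ordinal-trends model: closed-form subspace t-maximizer"),
    class = "tn_ortcva")
}

#' @export
print.tn_ortcva <- function(x, ...) {
  cat(sprintf("<tn_ortcva> %d components; paired t of expression differences = %.3f; %d ordinal violation(s)%s\n",
              x$n_components, x$paired_t, x$ordinal_violations,
              if (x$ridge_used) " [ridge fallback]" else ""))
  invisible(x)
}

#' Spatial similarity between a covariance pattern and a t-map
#'
#' Delegates to [similarity_test()] in both permutation directions, as in
#' the paired reporting of surrogate p-values.
#'
#' @param pattern a `brain_map` (e.g. the OrT/CVA pattern).
#' @param tmap a `brain_map` (e.g. the one-sample t map).
#' @param n_surr,seed,support,weight_power,voxel_cap,basis passed to
#'   [similarity_test()].
#' @return list with elements `permute_pattern` and `permute_tmap`, each a
#'   `tn_similarity`.
#' @export
pattern_vs_tmap <- function(pattern, tmap, n_surr = 10000, seed = 1,
                            support = "intersection_mask", weight_power = 2,
                            voxel_cap = 10000, basis = NULL) {
  a <- similarity_test(pattern, tmap, n_surr = n_surr, seed = seed,
                       permuted_side = "a", support = support,
                       weight_power = weight_power, voxel_cap = voxel_cap, basis = basis)
  b <- similarity_test(pattern, tmap, n_surr = n_surr, seed = seed + 1,
                       permuted_side = "b", support = support,
                       weight_power = weight_power, voxel_cap = voxel_cap, basis = basis)
  list(permute_pattern = a, permute_tmap = b)
}
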