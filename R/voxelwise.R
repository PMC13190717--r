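# Mass-univariate statistics on paired maps: subtraction images, sign-flip
# permutation one-sample t-maps, and voxel-wise covariate regression, with
# max-statistic family-wise-error correction.  The identity permutation is
# always counted in the null, so p >= 1/n_perm; with 2^n <= n_perm the
# sign-flip null is enumerated exactly and results are seed-independent.

#' Per-patient On-Off subtraction images
#'
#' @param cohort a `tn_cohort`.
#' @return list of `brain_map` difference maps (Stim-On minus Stim-Off).
#' @export
diff_maps <- function(cohort) {
  lapply(cohort$patients, function(p) {
    check_same_grid(p$on_map, p$off_map)
    map_with_values(p$on_map, map_values(p$on_map) - map_values(p$off_map))
  })
}

maps_to_matrix <- function(maps) {
  ref <- maps[[1]]
  for (m in maps[-1]) {
    check_same_grid(m, ref)
    if (!identical(m$mask, ref$mask))
      tn_stop("maps do not share a common mask", "tremornet_alignment_error")
  }
  do.call(rbind, lapply(maps, map_values))
}

all_sign_patterns <- function(n) {
  p <- 2L^n
  s <- matrix(1, p, n)
  for (j in seq_len(n)) s[, j] <- ifelse(bitwAnd(seq_len(p) - 1L, bitwShiftL(1L, j - 1L)) > 0, -1, 1)
  s
}

tail_crit <- function(tmat, tail) {
  # per-permutation extreme statistic over voxels (rows = permutations)
  tmat[!is.finite(tmat)] <- 0
  switch(tail,
         two_sided = apply(abs(tmat), 1, max),
         greater = apply(tmat, 1, max),
         less = apply(tmat, 1, min))
}

fwe_from_crit <- function(crit, t_obs, tail) {
  # FWE p per voxel: share of permutations whose extreme beats the voxel
  switch(tail,
         two_sided = vapply(abs(t_obs), function(t0) mean(crit >= t0), numeric(1)),
         greater = vapply(t_obs, function(t0) mean(crit >= t0), numeric(1)),
         less = vapply(t_obs, function(t0) mean(crit <= t0), numeric(1)))
}

new_stat_map <- function(template_map, infer_mask_vec, t_vec, p_vec, n_perm, tail,
                         df, exact, extra = list()) {
  mk <- function(vals) {
    arr <- array(0, dim = template_map$grid$shape)
    full <- numeric(sum(template_map$mask))
    full[infer_mask_vec] <- vals
    arr[template_map$mask] <- full
    infer <- array(FALSE, dim = template_map$grid$shape)
    tmp <- logical(sum(template_map$mask)); tmp[infer_mask_vec] <- TRUE
    infer[template_map$mask] <- tmp
    brain_map(template_map$grid, arr, infer)
  }
  out <- c(list(stat = mk(t_vec), p_fwe = mk(p_vec), n_permutations = n_perm,
                tail = tail, df = df, exact = exact,
                n_zero_variance = sum(template_map$mask) - length(infer_mask_vec)),
           extra)
  structure(out, class = "tn_stat_map")
}

#' @export
print.tn_stat_map <- function(x, ...) {
  tv <- map_values(x$stat)
  cat(sprintf("<tn_stat_map> tail=%s, df=%d, %s permutations%s; %d voxels (%d zero-variance dropped); max |t| = %.3f; min p_fwe = %.4g\n",
              x$tail, x$df, format(x$n_permutations, big.mark = ","),
              if (isTRUE(x$exact)) " (exact enumeration)" else "",
              length(tv), x$n_zero_variance, max(abs(tv)), min(map_values(x$p_fwe))))
  invisible(x)
}

#' One-sample permutation t-test across subject maps
#'
#' Per-voxel one-sample t statistics with a sign-flip null: whole subject
#' maps are multiplied by random signs, and voxel-wise family-wise-corrected
#' p-values are computed from the permutation distribution of the extreme
#' statistic over the mask.  Zero-variance voxels are excluded from
#' inference and counted in the result.
#'
#' @param maps list of `brain_map` on a common grid and mask (n >= 3).
#' @param n_perm number of sign-flip permutations (identity always included);
#'   when `2^n <= n_perm` all `2^n` sign patterns are enumerated.
#' @param seed integer seed (ignored under full enumeration).
#' @param tail `"two_sided"`, `"greater"` or `"less"`.
#' @return a `tn_stat_map` with `stat` (t) and `p_fwe` maps.
#' @export
one_sample_perm_t <- function(maps, n_perm = 10000, seed = 1,
                              tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(maps)
  if (n < 3) tn_stop("need >= 3 maps", "tremornet_insufficient_data")
  if (n_perm < 1) tn_stop("n_perm must be >= 1", "tremornet_config_error")
  Y <- maps_to_matrix(maps)
  v <- (colSums(Y^2) - n * colMeans(Y)^2) / (n - 1)
  # zero-variance = variance negligible relative to the second moment
  keep <- which(v > 1e-10 * pmax(colMeans(Y^2), 1e-300))
  if (length(keep) == 0) tn_stop("all voxels have zero variance", "tremornet_degenerate_data")
  Y <- Y[, keep, drop = FALSE]
  m_obs <- colMeans(Y)
  v_obs <- v[keep]
  t_obs <- m_obs / sqrt(v_obs / n)

  exact <- 2^n <= n_perm
  if (exact) {
    S <- all_sign_patterns(n)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), (n_perm - 1) * n, replace = TRUE), n_perm - 1, n)
    S <- rbind(rep(1, n), S)
  }
  P <- nrow(S)
  Q <- colMeans(Y^2)   # sign-invariant second moment
  crit <- numeric(P)
  chunk <- max(1L, floor(2e7 / length(keep)))
  for (start in seq(1L, P, by = chunk)) {
    rows <- start:min(P, start + chunk - 1L)
    Mp <- (S[rows, , drop = FALSE] %*% Y) / n
    Vp <- sweep(-Mp^2, 2, Q, "+") * n / (n - 1)
    Tp <- Mp / sqrt(Vp / n)
    crit[rows] <- tail_crit(Tp, tail)
  }
  p_fwe <- fwe_from_crit(crit, t_obs, tail)
  new_stat_map(maps[[1]], keep, t_obs, p_fwe, P, tail, df = n - 1L, exact = exact)
}

#' Voxel-wise simple linear regression against a subject covariate
#'
#' Per-voxel slope t statistics of map values on a covariate (intercept
#' included), with the null formed by permuting the covariate across
#' subjects and max-statistic FWE correction.
#'
#' @param maps list of `brain_map` on a common grid/mask (n >= 3).
#' @param covariate numeric vector, one value per map; must be non-constant.
#' @param n_perm number of permutations (identity always included).
#' @param seed integer seed.
#' @param tail `"two_sided"`, `"greater"` or `"less"`.
#' @return a `tn_stat_map` for the slope.
#' @export
voxelwise_regression <- function(maps, covariate, n_perm = 10000, seed = 1,
                                 tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(maps)
  if (n < 3) tn_stop("need >= 3 maps for residual df >= 1", "tremornet_insufficient_data")
  if (length(covariate) != n)
    tn_stop("covariate length must equal the number of maps", "tremornet_arg_error")
  if (stats::sd(covariate) == 0)
    tn_stop("covariate is constant; design is degenerate", "tremornet_degenerate_design")
  Y <- maps_to_matrix(maps)
  Yc <- sweep(Y, 2, colMeans(Y))
  ssY <- sqrt(colSums(Yc^2))
  keep <- which(ssY^2 > 1e-10 * pmax(colSums(Y^2), 1e-300))
  if (length(keep) == 0) tn_stop("all voxels have zero variance", "tremornet_degenerate_data")
  Yc <- Yc[, keep, drop = FALSE]
  ssY <- ssY[keep]
  xc <- covariate - mean(covariate)
  xn <- xc / sqrt(sum(xc^2))
  r_to_t <- function(r) {
    r <- pmin(pmax(r, -1), 1)
    t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    t
  }
  r_obs <- as.vector(crossprod(Yc, xn)) / ssY
  t_obs <- r_to_t(r_obs)

  set.seed(seed)
  perms <- matrix(0, n, n_perm)
  perms[, 1] <- xn
  for (j in seq_len(n_perm)[-1]) perms[, j] <- xn[sample.int(n)]
  crit <- numeric(n_perm)
  chunk <- max(1L, floor(2e7 / length(keep)))
  for (start in seq(1L, n_perm, by = chunk)) {
    cols <- start:min(n_perm, start + chunk - 1L)
    R <- crossprod(Yc, perms[, cols, drop = FALSE]) / ssY   # V x chunk
    Tm <- t(r_to_t(R))                                       # chunk x V
    crit[cols] <- tail_crit(Tm, tail)
  }
  p_fwe <- fwe_from_crit(crit, t_obs, tail)
  new_stat_map(maps[[1]], keep, t_obs, p_fwe, n_perm, tail, df = n - 2L, exact = FALSE)
}

#' Suprathreshold voxel summary of a stat map
#'
#' @param stat_map a `tn_stat_map`.
#' @param p_threshold report voxels with `p_fwe <=` this value.
#' @return tibble with voxel indices (1-based), world mm, t and FWE p.
#' @export
statmap_table <- function(stat_map, p_threshold = 0.05) {
  msk <- stat_map$p_fwe$mask
  sel <- which(msk & stat_map$p_fwe$data <= p_threshold, arr.ind = TRUE)
  grid <- stat_map$stat$grid
  mm <- sweep(sweep(sel - 1, 2, grid$voxel_size_mm, "*"), 2, grid$origin_mm, "+")
  tb <- tibble::tibble(i = sel[, 1], j = sel[, 2], k = sel[, 3],
                       x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
                       t = stat_map$stat$data[sel], p_fwe = stat_map$p_fwe$data[sel])
  tb[order(tb$p_fwe, -abs(tb$t)), ]
}
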