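# Voxel-wise linear model predicting per-patient metabolic change from
# sign-split normative connectivity and demeaned stimulation amplitude,
# with permutation-based (Freedman-Lane) cluster-level FWE correction in
# place of random-field theory.  Fixed-effects per-voxel OLS is used: with
# one observation per patient there is no repeated-measures structure.

#' Split a signed connectivity map into positive and negative parts
#'
#' Exact, lossless decomposition: voxels of the opposite sign are zeroed,
#' so `positive_part + negative_part` reconstructs the input.
#'
#' @param conn a `brain_map` of signed connectivity.
#' @return list of class `tn_sign_split` with `positive_part` (>= 0) and
#'   `negative_part` (<= 0), both `brain_map`s.
#' @export
split_signed <- function(conn) {
  v <- map_values(conn)
  structure(list(positive_part = map_with_values(conn, pmax(v, 0)),
                 negative_part = map_with_values(conn, pmin(v, 0))),
            class = "tn_sign_split")
}

# Vectorized per-voxel OLS with per-voxel design columns.
# cols: named list; each element an n-vector (shared across voxels) or an
# n x V matrix.  Returns list(inv = k x k x V array, ok = non-singular flag).
vox_ols_prep <- function(cols, n, V = NULL) {
  k <- length(cols)
  V <- max(vapply(cols, function(c) if (is.matrix(c)) ncol(c) else 1L, integer(1)), V)
  as_mat <- function(c) if (is.matrix(c)) c else matrix(c, n, V)
  Xs <- lapply(cols, as_mat)
  G <- array(0, dim = c(k, k, V))
  for (j in seq_len(k)) for (l in j:k) {
    g <- colSums(Xs[[j]] * Xs[[l]])
    G[j, l, ] <- g; G[l, j, ] <- g
  }
  inv <- array(NA_real_, dim = c(k, k, V))
  ok <- logical(V)
  for (v in seq_len(V)) {
    iv <- tryCatch(solve(G[, , v]), error = function(e) NULL)
    if (!is.null(iv) && all(is.finite(iv))) { inv[, , v] <- iv; ok[v] <- TRUE }
  }
  list(inv = inv, ok = ok, Xs = Xs, k = k, n = n, V = V, names = names(cols))
}

# t-statistics for every predictor at every voxel given a response matrix Y
# (n x V); fully vectorized over voxels using the precomputed inverses.
vox_ols_t <- function(prep, Y) {
  k <- prep$k; n <- prep$n; V <- prep$V
  xty <- matrix(0, k, V)
  for (j in seq_len(k)) xty[j, ] <- colSums(prep$Xs[[j]] * Y)
  beta <- matrix(0, k, V)
  for (j in seq_len(k)) for (l in seq_len(k))
    beta[j, ] <- beta[j, ] + prep$inv[j, l, ] * xty[l, ]
  rss <- colSums(Y^2) - colSums(beta * xty)
  sigma2 <- pmax(rss, 0) / (n - k)
  tmat <- matrix(NA_real_, k, V, dimnames = list(prep$names, NULL))
  for (j in seq_len(k)) {
    se <- sqrt(sigma2 * prep$inv[j, j, ])
    tj <- beta[j, ] / se
    tj[!is.finite(tj)] <- 0
    tmat[j, ] <- tj
  }
  tmat[, !prep$ok] <- NA_real_
  list(t = tmat, beta = beta, df = n - k)
}

#' Voxel-wise GLM of metabolic change on sign-split connectivity
#'
#' At each voxel, OLS across patients of the On-Off change on an intercept,
#' the positive connectivity part, the negative part, and demeaned
#' stimulation amplitude.  A connectivity predictor is dropped at voxels
#' where it is constant across patients (recorded in a support mask).
#'
#' @param delta_maps list of per-patient change `brain_map`s.
#' @param conn_maps list of per-patient signed connectivity `brain_map`s.
#' @param amplitude numeric vector of stimulation amplitudes (mA); demeaned
#'   across the cohort before fitting.  A constant amplitude is dropped
#'   with a warning.
#' @return object of class `tn_conn_glm`: `t_maps` (named list of
#'   `tn_stat_map`-style `brain_map` t maps), `support` (named list of
#'   logical arrays), `df` (per-voxel residual df array), plus internal
#'   state reused by [cluster_correct()].
#' @export
connectivity_glm <- function(delta_maps, conn_maps, amplitude) {
  n <- length(delta_maps)
  if (length(conn_maps) != n || length(amplitude) != n)
    tn_stop("delta_maps, conn_maps and amplitude must have equal length",
            "tremornet_arg_error")
  D <- maps_to_matrix(delta_maps)
  C <- maps_to_matrix(c(delta_maps[1], conn_maps))[-1, , drop = FALSE]
  ref <- delta_maps[[1]]
  V <- ncol(D)
  P <- pmax(C, 0); N <- pmin(C, 0)
  use_amp <- stats::sd(amplitude) > 0
  if (!use_amp)
    warning("amplitude is constant; demeaned to zero and dropped from the model")
  ampc <- if (use_amp) amplitude - mean(amplitude) else NULL
  n_base <- 2L + as.integer(use_amp)   # intercept (+ amplitude)
  if (n < n_base + 2L)
    tn_stop("too few patients for the model", "tremornet_insufficient_data")
  varying <- function(M) colSums(sweep(M, 2, colMeans(M))^2) > 1e-12 * pmax(colMeans(M^2), 1e-300)
  pos_ok <- varying(P); neg_ok <- varying(N)

  cats <- list(both = pos_ok & neg_ok, pos_only = pos_ok & !neg_ok,
               neg_only = !pos_ok & neg_ok, neither = !pos_ok & !neg_ok)
  t_pos <- rep(NA_real_, V); t_neg <- rep(NA_real_, V); t_amp <- rep(NA_real_, V)
  df_vec <- rep(NA_integer_, V)
  preps <- list()
  for (cat in names(cats)) {
    sel <- which(cats[[cat]])
    if (length(sel) == 0) next
    cols <- list(intercept = rep(1, n))
    if (cat %in% c("both", "pos_only")) cols$pos <- P[, sel, drop = FALSE]
    if (cat %in% c("both", "neg_only")) cols$neg <- N[, sel, drop = FALSE]
    if (use_amp) cols$amplitude <- ampc
    prep <- vox_ols_prep(cols, n)
    fit <- vox_ols_t(prep, D[, sel, drop = FALSE])
    if ("pos" %in% rownames(fit$t)) t_pos[sel] <- fit$t["pos", ]
    if ("neg" %in% rownames(fit$t)) t_neg[sel] <- fit$t["neg", ]
    if (use_amp) t_amp[sel] <- fit$t["amplitude", ]
    df_vec[sel] <- fit$df
    preps[[cat]] <- list(sel = sel, prep = prep)
  }
  to_map <- function(tv, okv) {
    if (sum(okv & !is.na(tv)) < 2) return(NULL)   # predictor absent (almost) everywhere
    arr <- array(0, dim = ref$grid$shape)
    m <- array(FALSE, dim = ref$grid$shape)
    full_ok <- logical(sum(ref$mask)); full_ok[okv & !is.na(tv)] <- TRUE
    full_t <- numeric(sum(ref$mask)); full_t[full_ok] <- tv[full_ok]
    arr[ref$mask] <- full_t; m[ref$mask] <- full_ok
    brain_map(ref$grid, arr, m)
  }
  support_arr <- function(okv) {
    m <- array(FALSE, dim = ref$grid$shape); m[ref$mask] <- okv; m
  }
  t_maps <- list(pos = to_map(t_pos, pos_ok), neg = to_map(t_neg, neg_ok))
  if (use_amp) t_maps$amplitude <- to_map(t_amp, rep(TRUE, V))
  structure(list(
    t_maps = t_maps,
    support = list(pos = support_arr(pos_ok), neg = support_arr(neg_ok)),
    df = df_vec, n = n, use_amplitude = use_amp,
    internal = list(D = D, P = P, N = N, ampc = ampc, preps = preps,
                    ref = ref, pos_ok = pos_ok, neg_ok = neg_ok,
                    t = list(pos = t_pos, neg = t_neg,
                             amplitude = if (use_amp) t_amp else NULL)),
    deviation = "fixed-effects per-voxel OLS; permutation (not RFT) cluster correction"),
    class = "tn_conn_glm")
}

neighbor_offsets <- function(connectivity) {
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, ]
  as.matrix(off)
}

# label connected components of a logical 3-D array; returns integer array
label_clusters <- function(supra, connectivity = 26) {
  d <- dim(supra)
  lab <- array(0L, dim = d)
  offs <- neighbor_offsets(connectivity)
  vox <- which(supra, arr.ind = TRUE)
  if (nrow(vox) == 0) return(lab)
  cur <- 0L
  for (r in seq_len(nrow(vox))) {
    if (lab[vox[r, 1], vox[r, 2], vox[r, 3]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(vox[r, ], ncol = 3)
    lab[vox[r, 1], vox[r, 2], vox[r, 3]] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, as.numeric(p), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        i <- nb[q, 1]; j <- nb[q, 2]; k <- nb[q, 3]
        if (supra[i, j, k] && lab[i, j, k] == 0L) {
          lab[i, j, k] <- cur
          queue <- rbind(queue, nb[q, , drop = FALSE])
        }
      }
    }
  }
  lab
}

cluster_stats_from_t <- function(t_vec, ok, crit, ref, connectivity, statistic) {
  supra_vec <- !is.na(t_vec) & ok & abs(t_vec) > crit
  supra <- array(FALSE, dim = ref$grid$shape)
  full <- logical(sum(ref$mask)); full[supra_vec] <- TRUE
  supra[ref$mask] <- full
  lab <- label_clusters(supra, connectivity)
  nlab <- max(lab)
  if (nlab == 0) return(list(lab = lab, stats = numeric(0), supra = supra))
  tarr <- array(0, dim = ref$grid$shape)
  fullt <- numeric(sum(ref$mask)); fullt[supra_vec] <- t_vec[supra_vec]
  tarr[ref$mask] <- fullt
  st <- vapply(seq_len(nlab), function(l) {
    if (statistic == "extent") sum(lab == l) else sum(abs(tarr[lab == l]))
  }, numeric(1))
  list(lab = lab, stats = st, supra = supra, tarr = tarr)
}

#' Permutation cluster-level FWE correction for a GLM predictor
#'
#' Suprathreshold voxels (|t| above the two-sided t-quantile for
#' `cluster_forming_p` at the voxel's residual df) are grouped by
#' 26-connectivity; the null distribution of the maximum cluster statistic
#' is built by Freedman-Lane residual permutation of the reduced model
#' (identity permutation included), and each observed cluster's p is the
#' share of permutation maxima at least as large.
#'
#' @param glm_fit a `tn_conn_glm` from [connectivity_glm()].
#' @param predictor `"pos"`, `"neg"` or `"amplitude"`.
#' @param cluster_forming_p two-sided voxel-level threshold (default 0.001).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param statistic `"extent"` (cluster size) or `"mass"` (sum of |t|).
#' @param connectivity 26 (default) or 6.
#' @return object of class `tn_cluster_result`: `clusters` tibble (label,
#'   n_voxels, stat, peak_t, peak mm, p), `labels` integer array,
#'   `threshold_p`, `statistic`, `connectivity`, `n_perm`, `correction`.
#' @export
cluster_correct <- function(glm_fit, predictor = c("pos", "neg", "amplitude"),
                            cluster_forming_p = 0.001, n_perm = 500, seed = 1,
                            statistic = c("extent", "mass"), connectivity = 26) {
  predictor <- match.arg(predictor)
  statistic <- match.arg(statistic)
  if (n_perm < 100) tn_stop("n_perm must be >= 100", "tremornet_config_error")
  if (predictor == "amplitude" && !glm_fit$use_amplitude)
    tn_stop("amplitude was dropped from the model", "tremornet_arg_error")
  int <- glm_fit$internal
  ref <- int$ref
  n <- glm_fit$n
  V <- ncol(int$D)
  ok <- switch(predictor, pos = int$pos_ok, neg = int$neg_ok, amplitude = rep(TRUE, V))
  df_vec <- glm_fit$df
  crit_vec <- rep(NA_real_, V)
  for (dfu in unique(stats::na.omit(df_vec)))
    crit_vec[which(df_vec == dfu)] <- stats::qt(1 - cluster_forming_p / 2, dfu)

  # observed clusters
  t_obs <- int$t[[predictor]]
  supra_crit <- crit_vec
  obs <- cluster_stats_from_t(t_obs, ok, supra_crit, ref, connectivity, statistic)

  # Freedman-Lane null: per category, fit reduced model (without the tested
  # predictor), permute its residuals, refit the full model
  set.seed(seed)
  perm_idx <- cbind(seq_len(n),
                    replicate(n_perm - 1, sample.int(n)))
  max_stat <- numeric(n_perm)
  t_perm_all <- matrix(NA_real_, n_perm, V)
  for (cat in names(int$preps)) {
    entry <- int$preps[[cat]]
    sel <- entry$sel
    prep <- entry$prep
    has_pred <- predictor %in% prep$names
    if (predictor != "amplitude" && !has_pred) next
    # reduced design: all columns except the tested predictor
    red_names <- setdiff(prep$names, predictor)
    red_cols <- lapply(red_names, function(nm) {
      X <- prep$Xs[[which(prep$names == nm)]]
      if (all(X == X[, 1])) X[, 1] else X
    })
    names(red_cols) <- red_names
    red_prep <- vox_ols_prep(red_cols, n, V = length(sel))
    Y <- int$D[, sel, drop = FALSE]
    redfit <- vox_ols_t(red_prep, Y)
    fitted <- matrix(0, n, length(sel))
    for (j in seq_along(red_names))
      fitted <- fitted + red_prep$Xs[[j]] * matrix(redfit$beta[j, ], n, length(sel), byrow = TRUE)
    resid <- Y - fitted
    for (pi in seq_len(n_perm)) {
      Ystar <- fitted + resid[perm_idx[, pi], , drop = FALSE]
      tp <- vox_ols_t(prep, Ystar)
      t_perm_all[pi, sel] <- tp$t[predictor, ]
    }
  }
  for (pi in seq_len(n_perm)) {
    cs <- cluster_stats_from_t(t_perm_all[pi, ], ok, crit_vec, ref, connectivity, statistic)
    max_stat[pi] <- if (length(cs$stats)) max(cs$stats) else 0
  }
  nlab <- length(obs$stats)
  clusters <- if (nlab == 0) {
    tibble::tibble(label = integer(0), n_voxels = integer(0), stat = numeric(0),
                   peak_t = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
                   z_mm = numeric(0), p = numeric(0))
  } else {
    rows <- lapply(seq_len(nlab), function(l) {
      vox <- which(obs$lab == l, arr.ind = TRUE)
      tv <- obs$tarr[obs$lab == l]
      pk <- vox[which.max(abs(tv)), ]
      mm <- ref$grid$origin_mm + (pk - 1) * ref$grid$voxel_size_mm
      tibble::tibble(label = l, n_voxels = nrow(vox), stat = obs$stats[l],
                     peak_t = tv[which.max(abs(tv))],
                     x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
                     p = mean(max_stat >= obs$stats[l]))
    })
    do.call(rbind, rows)
  }
  structure(list(predictor = predictor, clusters = clusters, labels = obs$lab,
                 threshold_p = cluster_forming_p, statistic = statistic,
                 connectivity = connectivity, n_perm = n_perm,
                 correction = "freedman_lane_permutation_max_cluster"),
            class = "tn_cluster_result")
}

#' @export
print.tn_cluster_result <- function(x, ...) {
  cat(sprintf("<tn_cluster_result> predictor %s: %d cluster(s), %s statistic, %d permutations\n",
              x$predictor, nrow(x$clusters), x$statistic, x$n_perm))
  if (nrow(x$clusters)) print(as.data.frame(x$clusters))
  invisible(x)
}
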