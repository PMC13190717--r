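# Spatial-autocorrelation-preserving surrogate inference for map-to-map
# similarity.  Surrogate maps share the source map's Moran spectrum: they
# are rebuilt from the eigenvectors of the doubly-centred spatial weight
# matrix (Moran eigenvector maps) with sign-randomized loadings, so the
# squared-loading profile across the spectrum -- and hence the spatial
# autocorrelation -- is preserved while the map itself is randomized.
# Similarity between maps is a voxel-wise Spearman rank correlation; its
# p-value is the share of surrogate correlations at least as large.

#' Inverse-power distance spatial weights over a mask
#'
#' w_ij = 1 / d_ij^power, with d the Euclidean distance between voxel
#' centres in mm and zero diagonal.
#'
#' @param grid a `volume_grid`.
#' @param mask logical array over the grid (or a `brain_map`, whose mask is
#'   used).
#' @param power distance exponent (default 2: inverse squared distance).
#' @param voxel_cap refuse masks larger than this many voxels (the dense
#'   eigenbasis is quadratic in memory; resample to a coarser grid first).
#' @return object of class `tn_spatial_weights` with fields `w` (dense
#'   symmetric matrix), `coordinates`, `n`, `power`, `grid_mm`.
#' @export
build_weights <- function(grid, mask, power = 2, voxel_cap = 10000) {
  if (inherits(mask, "brain_map")) { grid <- mask$grid; mask <- mask$mask }
  idx <- which(mask)
  n <- length(idx)
  if (n < 2) tn_stop("mask must contain >= 2 voxels", "tremornet_mask_error")
  if (n > voxel_cap)
    tn_stop(sprintf("mask has %d voxels (cap %d); resample to a coarser grid first",
                    n, voxel_cap), "tremornet_resource_error")
  co <- grid_coordinates(grid)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(co))
  if (any(d[upper.tri(d)] == 0))
    tn_stop("duplicate voxel coordinates give zero distances", "tremornet_degenerate_geometry")
  w <- 1 / d^power
  diag(w) <- 0
  dimnames(w) <- NULL
  structure(list(w = w, coordinates = co, n = n, power = power,
                 grid_mm = grid$voxel_size_mm),
            class = "tn_spatial_weights")
}

#' Moran's I spatial autocorrelation statistic
#'
#' I = (n / S0) * (z' W z) / (z' z) with z the centred values and
#' S0 the sum of all weights.
#'
#' @param x numeric vector over the in-mask voxels (same order as the
#'   weights), non-constant.
#' @param weights a `tn_spatial_weights`.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, weights) {
  stopifnot(inherits(weights, "tn_spatial_weights"))
  if (length(x) != weights$n)
    tn_stop("value vector length does not match the weights", "tremornet_arg_error")
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) tn_stop("Moran's I is undefined for a constant map", "tremornet_constant_map")
  s0 <- sum(weights$w)
  (weights$n / s0) * as.numeric(z %*% (weights$w %*% z)) / denom
}

#' Moran eigenvector basis of a spatial weight matrix
#'
#' Eigendecomposition of the doubly-centred weight matrix H W H.  The
#' eigenvector spanning the constant direction (zero eigenvalue) is dropped,
#' leaving n - 1 orthonormal patterns orthogonal to the constant vector,
#' sorted by eigenvalue descending.  Moran's I of eigenvector k equals
#' (n / S0) * eigenvalue_k.
#'
#' @param weights a `tn_spatial_weights`.
#' @return object of class `tn_moran_basis` with `vectors` (n x (n-1)),
#'   `values` (length n-1), `s0`, `n`.
#' @export
moran_eigenbasis <- function(weights) {
  stopifnot(inherits(weights, "tn_spatial_weights"))
  w <- weights$w
  rm_ <- rowMeans(w); gm <- mean(w)
  wc <- w - outer(rm_, rep(1, ncol(w))) - outer(rep(1, nrow(w)), rm_) + gm
  eg <- eigen(wc, symmetric = TRUE)
  if (any(!is.finite(eg$values)))
    tn_stop("eigendecomposition of the weight matrix failed", "tremornet_decomposition_error")
  # drop the eigenvector closest to the constant direction
  drop_k <- which.max(abs(colSums(eg$vectors)))
  keep <- setdiff(seq_len(weights$n), drop_k)
  structure(list(vectors = eg$vectors[, keep, drop = FALSE],
                 values = eg$values[keep], s0 = sum(w), n = weights$n),
            class = "tn_moran_basis")
}

#' Moran-spectrum-preserving surrogate maps (singleton procedure)
#'
#' The source vector is expanded in the Moran eigenbasis; each surrogate
#' randomizes the signs of the eigenvector loadings, preserving the
#' squared-loading profile (and hence the Moran spectrum), and is finally
#' re-standardized to the source mean and SD exactly.
#'
#' @param x numeric source vector (non-constant, same voxel order as basis).
#' @param basis a `tn_moran_basis` built on the same mask.
#' @param n_surr number of surrogates (>= 1).
#' @param seed integer seed.
#' @return n x n_surr matrix, one surrogate per column.
#' @export
msr_surrogates <- function(x, basis, n_surr, seed = 1) {
  stopifnot(inherits(basis, "tn_moran_basis"))
  if (n_surr < 1) tn_stop("n_surr must be >= 1", "tremornet_config_error")
  if (length(x) != basis$n) tn_stop("length(x) does not match the basis", "tremornet_arg_error")
  sx <- stats::sd(x)
  if (sx == 0) tn_stop("source map is constant", "tremornet_constant_map")
  z <- x - mean(x)
  r <- as.vector(crossprod(basis$vectors, z))
  set.seed(seed)
  eps <- matrix(sample(c(-1, 1), length(r) * n_surr, replace = TRUE), length(r), n_surr)
  s <- basis$vectors %*% (eps * r)
  mu <- colMeans(s)
  sdv <- apply(s, 2, stats::sd)
  sweep(sweep(s, 2, mu), 2, sdv / sx, "/") + mean(x)
}

rank_avg <- function(v) rank(v, ties.method = "average")

#' Spatial similarity test between two maps with an MSR null
#'
#' Spearman rank correlation over the support voxels; significance is the
#' share of Moran-spectrum-preserving surrogates of the permuted map whose
#' correlation with the fixed map is at least as large (ties count toward
#' the null).  A zero count is reported as the upper bound 1/n_surr with
#' `p_upper_bound = TRUE`.
#'
#' @param map_a,map_b `brain_map`s on a common grid.
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param permuted_side which map is replaced by surrogates (`"a"` or `"b"`).
#' @param tail `"greater"` (similarity, default) or `"two_sided"`.
#' @param support `"intersection_mask"` (both masks) or `"nonzero_b"`
#'   (additionally restricted to voxels where map_b is nonzero).
#' @param weight_power distance exponent of the spatial weights.
#' @param voxel_cap support-size cap for the dense eigenbasis.
#' @param basis optional precomputed `tn_moran_basis` on exactly the support
#'   voxels (reuse across repeated tests on one mask).
#' @return object of class `tn_similarity` with fields `rho_obs`, `p`,
#'   `p_upper_bound`, `n_surrogates`, `permuted_side`, `tail`, `support`,
#'   `n_voxels`, `seed`, `weight_power`, `grid_mm`, `procedure`.
#' @export
similarity_test <- function(map_a, map_b, n_surr = 10000, seed = 1,
                            permuted_side = c("a", "b"),
                            tail = c("greater", "two_sided"),
                            support = c("intersection_mask", "nonzero_b"),
                            weight_power = 2, voxel_cap = 10000, basis = NULL) {
  permuted_side <- match.arg(permuted_side)
  tail <- match.arg(tail)
  support <- match.arg(support)
  check_same_grid(map_a, map_b)
  supp <- map_a$mask & map_b$mask
  if (support == "nonzero_b") supp <- supp & map_b$data != 0
  if (sum(supp) < 10) tn_stop("support has fewer than 10 voxels", "tremornet_support_error")
  xa <- map_a$data[supp]; xb <- map_b$data[supp]
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    tn_stop("a map is constant on the support; correlation undefined",
            "tremornet_constant_map")
  rho_obs <- stats::cor(xa, xb, method = "spearman")
  if (is.null(basis)) {
    w <- build_weights(map_a$grid, supp, power = weight_power, voxel_cap = voxel_cap)
    basis <- moran_eigenbasis(w)
  } else if (basis$n != sum(supp)) {
    tn_stop("precomputed basis does not match the support size", "tremornet_arg_error")
  }
  src <- if (permuted_side == "a") xa else xb
  fixed <- if (permuted_side == "a") xb else xa
  surr <- msr_surrogates(src, basis, n_surr, seed = seed)
  rf <- rank_avg(fixed)
  ranks <- apply(surr, 2, rank_avg)
  rho_s <- as.vector(stats::cor(ranks, rf))
  count <- if (tail == "greater") sum(rho_s >= rho_obs) else sum(abs(rho_s) >= abs(rho_obs))
  structure(list(rho_obs = rho_obs, p = max(count, 1L) / n_surr,
                 p_upper_bound = count == 0L, n_surrogates = n_surr,
                 permuted_side = permuted_side, tail = tail, support = support,
                 n_voxels = sum(supp), seed = seed, weight_power = weight_power,
                 grid_mm = map_a$grid$voxel_size_mm, procedure = "singleton"),
            class = "tn_similarity")
}

#' @export
print.tn_similarity <- function(x, ...) {
  cat(sprintf("<tn_similarity> Spearman rho = %.4f; %s%.4g (%s surrogates, side %s, %s, %d voxels)\n",
              x$rho_obs, if (x$p_upper_bound) "p < " else "p = ", x$p,
              format(x$n_surrogates, big.mark = ","), x$permuted_side, x$tail, x$n_voxels))
  invisible(x)
}

#' Serialize a similarity result to JSON
#' @param result a `tn_similarity`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
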