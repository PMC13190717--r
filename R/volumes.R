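# Volumetric data model and preprocessing operators.
#
# All grids are axis-aligned: world coordinate of voxel index (i,j,k)
# (0-based) is origin_mm + index * voxel_size_mm.  Rotated or sheared
# headers are rejected rather than silently resampled.

tn_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "tremornet_error"), call = call))
}

#' Define an axis-aligned volume grid
#'
#' @param shape integer vector of length 3 (nx, ny, nz), all >= 1.
#' @param voxel_size_mm positive numeric vector of length 3 (mm per voxel).
#' @param origin_mm numeric vector of length 3; world-mm coordinate of the
#'   centre of voxel index (0, 0, 0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm, origin_mm = -(shape - 1) / 2 * voxel_size_mm) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(rep_len(voxel_size_mm, 3L))
  origin_mm <- as.numeric(rep_len(origin_mm, 3L))
  if (length(shape) != 3L || any(shape < 1L))
    tn_stop("'shape' must be three integers >= 1", "tremornet_grid_error")
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    tn_stop("'voxel_size_mm' must be three positive reals", "tremornet_grid_error")
  if (any(!is.finite(origin_mm)))
    tn_stop("'origin_mm' must be finite", "tremornet_grid_error")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %g x %g x %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' World-mm coordinates of grid voxels
#'
#' @param grid a `volume_grid`.
#' @param axis axis index 1..3, or NULL for the full coordinate matrix of
#'   every voxel (column-major order), one row per voxel.
#' @return numeric vector (per-axis centres) or an n x 3 matrix.
#' @export
grid_coordinates <- function(grid, axis = NULL) {
  ax_coord <- function(a) grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_size_mm[a]
  if (!is.null(axis)) return(ax_coord(axis))
  xs <- ax_coord(1); ys <- ax_coord(2); zs <- ax_coord(3)
  cbind(x = rep(xs, times = length(ys) * length(zs)),
        y = rep(rep(ys, each = length(xs)), times = length(zs)),
        z = rep(zs, each = length(xs) * length(ys)))
}

#' Construct a masked brain map
#'
#' A `brain_map` carries one real value per in-mask voxel of an axis-aligned
#' grid.  Out-of-mask voxels are stored as 0 and carry no value.
#'
#' @param grid a `volume_grid`.
#' @param data numeric array with dim = grid$shape (or a vector of in-mask
#'   values when `mask` is given).
#' @param mask logical array with dim = grid$shape; defaults to all-TRUE.
#' @return An object of class `brain_map` with fields `grid`, `mask`, `data`.
#' @export
brain_map <- function(grid, data, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(mask)) mask <- array(TRUE, dim = grid$shape)
  mask <- array(as.logical(mask), dim = grid$shape)
  if (anyNA(mask)) tn_stop("mask may not contain NA", "tremornet_mask_error")
  if (sum(mask) < 1L) tn_stop("mask must contain >= 1 voxel", "tremornet_mask_error")
  if (is.array(data) || length(data) == prod(grid$shape)) {
    arr <- array(as.numeric(data), dim = grid$shape)
  } else if (length(data) == sum(mask)) {
    arr <- array(0, dim = grid$shape)
    arr[mask] <- as.numeric(data)
  } else {
    tn_stop("'data' must match the grid or the mask voxel count", "tremornet_data_error")
  }
  if (any(!is.finite(arr[mask])))
    tn_stop("in-mask values must all be finite", "tremornet_data_error")
  arr[!mask] <- 0
  structure(list(grid = grid, mask = mask, data = arr), class = "brain_map")
}

#' In-mask values of a brain map
#' @param map a `brain_map`.
#' @return numeric vector of the values at in-mask voxels (column-major order).
#' @export
map_values <- function(map) map$data[map$mask]

#' Replace in-mask values, keeping grid and mask
#' @param map a `brain_map`.
#' @param values numeric vector, one value per in-mask voxel.
#' @return a new `brain_map`.
#' @export
map_with_values <- function(map, values) {
  stopifnot(length(values) == sum(map$mask))
  arr <- array(0, dim = map$grid$shape)
  arr[map$mask] <- values
  brain_map(map$grid, arr, map$mask)
}

#' @export
print.brain_map <- function(x, ...) {
  v <- map_values(x)
  cat(sprintf("<brain_map> %d x %d x %d @ %g mm; %d in-mask voxels; range [%.4g, %.4g]\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$voxel_size_mm[1], sum(x$mask), min(v), max(v)))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!grids_equal(a$grid, b$grid))
    tn_stop("maps are not on the same grid", "tremornet_alignment_error")
  invisible(TRUE)
}

nifti_affine <- function(grid) {
  aff <- diag(c(grid$voxel_size_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' Read a 3-D NIfTI volume as a brain map
#'
#' Only axis-aligned headers (diagonal rotation part with positive entries)
#' are supported; anything else raises an unsupported-orientation error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask either NULL (all voxels in-mask; values must then be finite),
#'   the string `"nonzero"` (mask = nonzero finite voxels), or a logical
#'   array / `brain_map` giving the mask.
#' @return a `brain_map`.
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    tn_stop(sprintf("expected a 3-D volume, got %d dimensions", length(d)),
            "tremornet_dim_error")
  aff <- RNifti::xform(img)
  rot <- unname(aff[1:3, 1:3])
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))) || any(diag(rot) <= 0))
    tn_stop("only axis-aligned (diagonal, positive) orientations are supported",
            "tremornet_orientation_error")
  grid <- volume_grid(d, diag(rot), aff[1:3, 4])
  arr <- as.array(img)
  if (identical(mask, "nonzero")) {
    m <- is.finite(arr) & arr != 0
  } else if (inherits(mask, "brain_map")) {
    m <- mask$mask
  } else if (!is.null(mask)) {
    m <- array(as.logical(mask), dim = d)
  } else {
    m <- array(TRUE, dim = d)
  }
  arr[!m] <- 0
  brain_map(grid, arr, m)
}

#' Write a brain map as a float32 NIfTI volume
#'
#' Out-of-mask voxels are written as 0; write the mask separately with
#' `write_mask()` if it must be recovered.
#'
#' @param map a `brain_map`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path) {
  img <- RNifti::asNifti(map$data)
  RNifti::pixdim(img) <- map$grid$voxel_size_mm
  aff <- nifti_affine(map$grid)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a mask as a uint8 NIfTI volume
#' @param map a `brain_map` (its mask is written) or a logical array plus `grid`.
#' @param path output path.
#' @param grid required when `map` is a bare logical array.
#' @return `path`, invisibly.
#' @export
write_mask <- function(map, path, grid = NULL) {
  if (inherits(map, "brain_map")) {
    m <- map$mask; grid <- map$grid
  } else m <- map
  img <- RNifti::asNifti(array(as.integer(m), dim = grid$shape))
  RNifti::pixdim(img) <- grid$voxel_size_mm
  aff <- nifti_affine(grid)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Intensity-normalize a map to a reference region
#'
#' Divides every value by the mean over `reference_mask` (e.g. a brain
#' parenchyma mask), so that the reference-region mean becomes exactly 1.
#'
#' @param map a `brain_map`.
#' @param reference_mask logical array (subset of `map$mask`) or `brain_map`.
#' @return the normalized `brain_map`.
#' @export
intensity_normalize <- function(map, reference_mask = map$mask) {
  ref <- if (inherits(reference_mask, "brain_map")) reference_mask$mask else
    array(as.logical(reference_mask), dim = map$grid$shape)
  if (any(ref & !map$mask))
    tn_stop("reference mask must be a subset of the map mask", "tremornet_mask_error")
  mu <- mean(map$data[ref])
  if (!is.finite(mu) || abs(mu) <= 1e-12 * max(mean(abs(map$data[ref])), .Machine$double.xmin))
    tn_stop("reference-region mean is zero; normalization is degenerate",
            "tremornet_degenerate_normalization")
  map_with_values(map, map_values(map) / mu)
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# 1-D convolution of a 3-D array along `axis` with zero padding.
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  n <- d[axis]
  idx_all <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (o in (-r):r) {
    w <- kernel[o + r + 1L]
    lo <- max(1L, 1L + o); hi <- min(n, n + o)
    if (lo > hi) next
    src <- lo:hi
    dst <- src - o
    ia_src <- idx_all; ia_src[[axis]] <- src
    ia_dst <- idx_all; ia_dst[[axis]] <- dst
    out[ia_dst[[1]], ia_dst[[2]], ia_dst[[3]]] <-
      out[ia_dst[[1]], ia_dst[[2]], ia_dst[[3]]] +
      w * arr[ia_src[[1]], ia_src[[2]], ia_src[[3]]]
  }
  out
}

#' Gaussian smoothing of a brain map
#'
#' Separable Gaussian convolution with sigma_mm = fwhm / (2 sqrt(2 ln 2)) per
#' axis, converted to voxel units by the grid's voxel size.  Smoothing is
#' computed on the full grid with out-of-mask voxels treated as 0, and the
#' result is re-masked (no mask-weighted renormalization).
#'
#' @param map a `brain_map`.
#' @param fwhm_mm nonnegative full-width-at-half-maximum in mm (scalar or
#'   per-axis triple).  `fwhm_mm = 0` is the identity.
#' @return the smoothed `brain_map`.
#' @export
gaussian_smooth <- function(map, fwhm_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm < 0)) tn_stop("'fwhm_mm' must be >= 0", "tremornet_arg_error")
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / map$grid$voxel_size_mm
  arr <- map$data
  for (ax in 1:3) arr <- conv_axis(arr, gauss_kernel_1d(sig_vox[ax]), ax)
  arr[!map$mask] <- 0
  brain_map(map$grid, arr, map$mask)
}

#' Block-mean down-sampling to a coarser grid
#'
#' The target voxel size must be an integer multiple of the source voxel size
#' on every axis.  Each output voxel is the mean of the in-mask source voxels
#' of its block; the output mask is true iff at least half of the block's
#' source voxels are in-mask.
#'
#' @param map a `brain_map`.
#' @param target_voxel_mm positive target voxel size in mm (scalar or triple).
#' @return the resampled `brain_map`.
#' @export
resample <- function(map, target_voxel_mm) {
  target <- rep_len(as.numeric(target_voxel_mm), 3L)
  f <- target / map$grid$voxel_size_mm
  if (any(abs(f - round(f)) > 1e-8) || any(round(f) < 1))
    tn_stop("target voxel size must be an integer multiple of the source voxel size",
            "tremornet_resample_error")
  f <- as.integer(round(f))
  if (all(f == 1L)) return(map)
  src_shape <- map$grid$shape
  out_shape <- as.integer(ceiling(src_shape / f))
  block_of <- function(i, a) (i - 1L) %/% f[a] + 1L     # 1-based output index per source index
  bx <- block_of(seq_len(src_shape[1]), 1)
  by <- block_of(seq_len(src_shape[2]), 2)
  bz <- block_of(seq_len(src_shape[3]), 3)
  block_id <- array(0L, dim = src_shape)
  block_id[] <- bx + (rep(by, each = src_shape[1]) - 1L) * out_shape[1] +
    (rep(bz, each = src_shape[1] * src_shape[2]) - 1L) * out_shape[1] * out_shape[2]
  nb <- prod(out_shape)
  block_total <- tabulate(block_id, nbins = nb)
  in_count <- tabulate(block_id[map$mask], nbins = nb)
  sums <- unname(rowsum(as.vector(map$data * map$mask), group = as.vector(block_id)))
  sums_full <- numeric(nb); sums_full[sort(unique(as.vector(block_id)))] <- sums
  out_mask <- in_count >= block_total / 2 & in_count > 0
  out_vals <- ifelse(in_count > 0, sums_full / pmax(in_count, 1L), 0)
  out_vals[!out_mask] <- 0
  new_grid <- volume_grid(out_shape, target,
                          map$grid$origin_mm + (f - 1) / 2 * map$grid$voxel_size_mm)
  brain_map(new_grid, array(out_vals, dim = out_shape), array(out_mask, dim = out_shape))
}

# reflection partner index (1-based) about world x = 0, or NA when out of range
mirror_index <- function(grid) {
  dx <- grid$voxel_size_mm[1]; ox <- grid$origin_mm[1]; nx <- grid$shape[1]
  m <- -2 * ox / dx            # j0 + i0 = m for partners (0-based)
  if (abs(m - round(m)) > 1e-6)
    tn_stop("grid is not resolvable by reflection about x = 0", "tremornet_asymmetric_grid")
  j <- round(m) - (seq_len(nx) - 1L) + 1L
  j[j < 1L | j > nx] <- NA_integer_
  if (all(is.na(j)))
    tn_stop("no voxel pair straddles x = 0 under reflection", "tremornet_asymmetric_grid")
  j
}

#' Hemisphere mirroring about the midsagittal plane
#'
#' The first grid axis is the left-right axis and the midsagittal plane is
#' world x = 0; the reflection is rigid.  A voxel is "left" iff its world
#' x-coordinate is < 0; voxels at exactly x = 0 belong to neither hemisphere
#' and are masked out by `average_to_left`.
#'
#' @param map a `brain_map`.
#' @param mode `"left_to_right_bilateral"`: out-of-mask voxels whose mirror
#'   image is in-mask receive the mirrored value (in-mask voxels keep their
#'   value), producing a bilateral map. `"average_to_left"`: each left
#'   in-mask voxel becomes the mean of itself and its in-mask mirror partner;
#'   the right hemisphere is masked out.
#' @return the mirrored `brain_map`.
#' @export
mirror <- function(map, mode = c("left_to_right_bilateral", "average_to_left")) {
  mode <- match.arg(mode)
  j <- mirror_index(map$grid)
  xs <- grid_coordinates(map$grid, axis = 1)
  d <- map$grid$shape
  refl_data <- array(0, dim = d); refl_mask <- array(FALSE, dim = d)
  ok <- which(!is.na(j))
  refl_data[ok, , ] <- map$data[j[ok], , ]
  refl_mask[ok, , ] <- map$mask[j[ok], , ]
  if (mode == "left_to_right_bilateral") {
    fill <- !map$mask & refl_mask
    arr <- map$data; arr[fill] <- refl_data[fill]
    brain_map(map$grid, arr, map$mask | fill)
  } else {
    left <- array(xs < 0, dim = d)            # axis 1 varies fastest
    keep <- map$mask & left
    if (!any(keep)) tn_stop("map has no left-hemisphere voxels", "tremornet_input_error")
    both <- keep & refl_mask
    arr <- array(0, dim = d)
    arr[keep] <- map$data[keep]
    arr[both] <- (map$data[both] + refl_data[both]) / 2
    brain_map(map$grid, arr, keep)
  }
}
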