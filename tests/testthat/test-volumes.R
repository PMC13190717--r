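# volumetric container, NIfTI I/O and preprocessing operators

test_that("NIfTI round trip preserves values, grid and mask handling", {
  m <- random_map(seed = 11)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  m2 <- read_volume(f)
  expect_equal(m2$grid$shape, m$grid$shape)
  expect_equal(m2$grid$voxel_size_mm, m$grid$voxel_size_mm, tolerance = 1e-5)
  expect_equal(m2$grid$origin_mm, m$grid$origin_mm, tolerance = 1e-4)
  expect_lt(max(abs(m2$data - m$data)), 1e-5)    # float32 storage

  # nonzero mask excludes zeros and non-finite voxels
  arr <- m$data; arr[1, 1, 1] <- 0; arr[2, 2, 2] <- NaN
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- m$grid$voxel_size_mm
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2)
  m3 <- read_volume(f2, mask = "nonzero")
  expect_false(m3$mask[1, 1, 1])
  expect_false(m3$mask[2, 2, 2])
  expect_equal(sum(m3$mask), prod(m$grid$shape) - 2L)
})

test_that("read_volume rejects 4-D input and rotated orientations", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(read_volume(f), class = "tremornet_dim_error")

  arr <- array(rnorm(64), c(4, 4, 4))
  img <- RNifti::asNifti(arr)
  th <- pi / 7
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  RNifti::qform(img) <- structure(rot, code = 2L)
  RNifti::sform(img) <- structure(rot, code = 2L)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2)
  expect_error(read_volume(f2), class = "tremornet_orientation_error")
})

test_that("intensity normalization divides by the reference mean and is idempotent", {
  g <- tiny_grid(c(4, 4, 4), 2)
  cm <- brain_map(g, array(7, c(4, 4, 4)))
  expect_equal(map_values(intensity_normalize(cm)), rep(1, 64))

  ref <- array(FALSE, c(4, 4, 4)); ref[1, 1, 1] <- ref[2, 1, 1] <- TRUE
  vals <- array(2, c(4, 4, 4)); vals[1, 1, 1] <- 1; vals[2, 1, 1] <- 3
  m <- brain_map(g, vals)
  nm <- intensity_normalize(m, ref)
  expect_equal(nm$data[1, 1, 1], 0.5)
  expect_equal(nm$data[2, 1, 1], 1.5)

  r <- random_map(seed = 2)
  n1 <- intensity_normalize(r)
  expect_equal(mean(map_values(n1)), 1, tolerance = 1e-12)
  n2 <- intensity_normalize(n1)
  expect_equal(map_values(n2), map_values(n1), tolerance = 1e-12)

  zm <- map_with_values(r, map_values(r) - mean(map_values(r)))
  expect_error(intensity_normalize(zm), class = "tremornet_degenerate_normalization")
})

test_that("gaussian smoothing: zero-width identity, kernel normalization, constant invariance", {
  m <- random_map(seed = 3)
  expect_equal(gaussian_smooth(m, 0)$data, m$data)

  g <- tiny_grid(c(11, 11, 11), 2)
  arr <- array(0, c(11, 11, 11)); arr[6, 6, 6] <- 1
  sm <- gaussian_smooth(brain_map(g, arr), 5)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  expect_equal(which.max(sm$data), which.max(arr))

  # constant map is unchanged away from the zero-padded boundary
  cm <- brain_map(g, array(3.5, c(11, 11, 11)))
  smc <- gaussian_smooth(cm, 4)
  expect_equal(smc$data[5:7, 5:7, 5:7], cm$data[5:7, 5:7, 5:7], tolerance = 1e-9)
})

test_that("block resampling averages in-mask voxels with the majority mask rule", {
  g <- tiny_grid(c(2, 2, 2), 2)
  vals <- array(c(0, 0, 0, 0, 8, 8, 8, 8), c(2, 2, 2))
  r <- resample(brain_map(g, vals), 4)
  expect_equal(r$grid$shape, c(1L, 1L, 1L))
  expect_equal(as.numeric(r$data), 4)

  msk <- array(FALSE, c(2, 2, 2)); msk[1:3] <- TRUE   # 3 of 8 in-mask
  g4 <- tiny_grid(c(4, 2, 2), 2)
  msk4 <- array(TRUE, c(4, 2, 2)); msk4[3:4, , ] <- FALSE
  msk4[3, 1, 1] <- TRUE                               # second block: 1 of 8
  r2 <- resample(brain_map(g4, array(1, c(4, 2, 2)), msk4), 4)
  expect_true(r2$mask[1, 1, 1])
  expect_false(r2$mask[2, 1, 1])

  cm <- brain_map(tiny_grid(c(4, 4, 4), 2), array(2.5, c(4, 4, 4)))
  rc <- resample(cm, 4)
  expect_true(all(rc$data == 2.5))
  expect_equal(mean(map_values(rc)), mean(map_values(cm)))

  expect_error(resample(cm, 3), class = "tremornet_resample_error")
})

test_that("mirroring: symmetry fixed point, averaging, composition identity, errors", {
  g <- tiny_grid(c(8, 4, 4), 2)              # x in -7..7, symmetric about 0
  set.seed(4)
  arr <- array(rnorm(128), c(8, 4, 4))
  sym <- arr
  for (i in 1:8) sym[i, , ] <- (arr[i, , ] + arr[9 - i, , ]) / 2
  ms <- brain_map(g, sym)
  expect_equal(mirror(ms, "left_to_right_bilateral")$data, ms$data)

  m <- brain_map(g, arr)
  av <- mirror(m, "average_to_left")
  expect_equal(av$data[2, 3, 1], (arr[2, 3, 1] + arr[7, 3, 1]) / 2)
  xs <- grid_coordinates(g, axis = 1)
  expect_true(all(which(apply(av$mask, 1, any)) %in% which(xs < 0)))

  lmask <- array(FALSE, c(8, 4, 4)); lmask[1:4, , ] <- TRUE
  lo <- brain_map(g, arr, lmask)
  rec <- mirror(mirror(lo, "left_to_right_bilateral"), "average_to_left")
  expect_identical(rec$mask, lmask)
  expect_equal(rec$data[lmask], lo$data[lmask], tolerance = 1e-12)

  g_asym <- volume_grid(c(8, 4, 4), 2, origin_mm = c(-7.5, -3, -3))
  expect_error(mirror(brain_map(g_asym, arr), "average_to_left"),
               class = "tremornet_asymmetric_grid")
})
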