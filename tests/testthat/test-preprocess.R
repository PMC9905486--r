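test_that("stack write/read round trip preserves intensities and calibration", {
  ph <- quiet_phantom()
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(ph$volume, path)
  back <- read_stack(path)
  expect_equal(back$intensities, ph$volume$intensities, tolerance = 1e-6)
  expect_equal(back$pitch, ph$volume$pitch)
})

test_that("uncalibrated TIFFs need explicit pitches and axis specs must be sane", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(runif(12), 3), matrix(runif(12), 3)), path)
  expect_error(read_stack(path), "pitch")
  v <- read_stack(path, pitch = c(2, 1, 1))
  expect_equal(unname(v$pitch), c(2, 1, 1))
  expect_equal(dim(v), c(2, 3, 4))
  expect_error(read_stack(path, axis_spec = "zz"), "axis_spec")
  expect_error(read_stack("no-such-file.tif"), "read")
})

test_that("isotropic rescaling preserves extent, constants and fixed points", {
  v <- vnc_volume(array(runif(4 * 6 * 6), c(4, 6, 6)), pitch = c(2, 1, 1))
  iso <- rescale_isotropic(v, 1)
  expect_equal(unname(iso$pitch), c(1, 1, 1))
  expect_equal(dim(iso)[1], 8)               # AP plane count doubles
  expect_equal(dim(iso)[2:3], c(6, 6))

  same <- rescale_isotropic(iso, 1)
  expect_equal(same$intensities, iso$intensities, tolerance = 1e-12)

  const <- vnc_volume(array(3.7, c(5, 4, 4)), pitch = c(1.5, 0.5, 0.5))
  out <- rescale_isotropic(const, 0.5)
  expect_true(all(abs(out$intensities - 3.7) < 1e-12))
})

test_that("cropping honours explicit boxes and finds the foreground automatically", {
  ph <- quiet_phantom()
  vol <- ph$volume
  full <- crop_vnc(vol, box = cbind(rep(1, 3), dim(vol)))
  expect_equal(full$intensities, vol$intensities)

  auto <- crop_vnc(vol)
  thr <- max(vol$intensities) * 0.5
  fg <- which(vol$intensities > thr, arr.ind = TRUE)
  kept <- dim(auto)[1:3]
  # bright fascicle voxels survive the crop on every axis
  expect_lte(diff(range(fg[, 2])) + 1, kept[2])
  expect_lte(diff(range(fg[, 3])) + 1, kept[3])
  expect_error(crop_vnc(vnc_volume(array(0, c(4, 4, 4)), 1)), "foreground")
  expect_error(crop_vnc(vol, box = cbind(c(1, 1, 1), dim(vol) + 1)), "box")
})

test_that("hemisegment split follows the midline convention and partitions the stack", {
  ph <- quiet_phantom()
  left <- split_hemisegment(ph$volume, "left")
  right <- split_hemisegment(ph$volume, "right")
  w <- dim(ph$volume)[3]
  expect_equal(dim(left)[3] + dim(right)[3], w)
  # mirror-symmetric phantom: left equals ML-flipped right
  flipped <- right$intensities[, , rev(seq_len(dim(right)[3]))]
  expect_equal(left$intensities, flipped, tolerance = 1e-12)

  odd <- vnc_volume(array(seq_len(2 * 2 * 5), c(2, 2, 5)), 1)
  expect_equal(dim(split_hemisegment(odd, "left"))[3], 3)  # ceiling(5/2)
  re <- array(0, dim(odd))
  re[, , 1:3] <- split_hemisegment(odd, "left")$intensities
  re[, , 4:5] <- split_hemisegment(odd, "right")$intensities
  expect_equal(re, odd$intensities + 0)
  expect_error(split_hemisegment(vnc_volume(array(1, c(2, 2, 1)), 1)), "ML")
})

test_that("binning equals a brute-force per-bin maximum and drops partial bins", {
  set.seed(11)
  x <- array(runif(23 * 3 * 4), c(23, 3, 4))
  v <- vnc_volume(x, 1)
  slabs <- bin_and_project(v, bin_length = 5)
  expect_equal(length(slabs), 4)             # trailing 3-plane bin dropped
  expect_equal(slabs$planes_per_bin, 5L)
  for (b in 1:4) {
    expect_identical(slabs$sections[[b]],
                     apply(x[((b - 1) * 5 + 1):(b * 5), , ], c(2, 3), max))
  }

  # a single bright voxel surfaces only in its own bin
  y <- array(0, c(20, 3, 3)); y[13, 2, 2] <- 5
  s <- bin_and_project(vnc_volume(y + 0.01, 1), bin_length = 4)
  bright <- vapply(s$sections, max, numeric(1))
  expect_equal(which(bright > 1), 4L)        # plane 13 -> bin ceiling(13/4)

  const <- bin_and_project(vnc_volume(array(2, c(10, 3, 3)), 1), 2)
  for (sec in const$sections) expect_true(all(sec == 2))
  expect_error(bin_and_project(vnc_volume(array(1, c(3, 2, 2)), 1), 2.9), "bins")
  aniso <- vnc_volume(array(1, c(10, 3, 3)), c(2, 1, 1))
  expect_error(bin_and_project(aniso, 2), "isotropic")
})

test_that("slab series survive a write/read round trip", {
  slabs <- bin_and_project(quiet_phantom()$volume, 2.2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_slabs(slabs, path)
  back <- read_slabs(path)
  expect_equal(back$bin_length, slabs$bin_length)
  expect_equal(back$planes_per_bin, slabs$planes_per_bin)
  expect_equal(back$sections[[3]], slabs$sections[[3]], tolerance = 1e-6)
})

test_that("VNC length recovers the planted AP extent and scales with the axis", {
  ph <- quiet_phantom()
  len <- vnc_length(ph$volume)
  planted <- tiny_params()$n_segments * tiny_params()$period
  expect_lte(abs(len - planted), 2 * ph$volume$pitch[["ap"]])

  stretched <- vnc_volume(ph$volume$intensities,
                          ph$volume$pitch * c(2, 1, 1))
  expect_equal(vnc_length(stretched), 2 * len)
  expect_error(vnc_length(vnc_volume(array(0, c(4, 4, 4)), 1)), "foreground")
})
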