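test_that("ROI integrated density follows the IntDen convention", {
  img <- matrix(3, 40, 20)
  attr(img, "pitch") <- 0.5
  rois <- roi_spec("node", center_ap = c(5, 10), center_ml = c(5, 5), size = 2)
  res <- integrated_density(img, rois)
  # 2 μm square at 0.5 μm pitch = 16 pixels of value 3, pixel area 0.25
  expect_equal(res$integrated_density, rep(3 * 16 * 0.25, 2))
  expect_equal(res$mean_density, rep(3, 2))
  gl <- glance(res)
  expect_equal(gl$mean_integrated_density, 12)
  expect_equal(gl$sd_integrated_density, 0)

  empty <- integrated_density(img, roi_spec(character(0), numeric(0),
                                            numeric(0), 2))
  expect_equal(nrow(empty), 0)
  expect_error(
    integrated_density(img, roi_spec("node", 100, 5, 2)), "node #1")
})

test_that("density scales linearly with image intensity", {
  set.seed(3)
  img <- matrix(runif(800), 40, 20)
  attr(img, "pitch") <- 1
  rois <- roi_spec(c("node", "internode"), c(10, 30), c(10, 10), 6)
  res1 <- integrated_density(img, rois)
  res5 <- integrated_density(img * 5, rois)
  expect_equal(res5$integrated_density, 5 * res1$integrated_density)
})

test_that("segment densities tile the image and match brute-force sums", {
  set.seed(8)
  img <- matrix(runif(50 * 10), 50, 10)
  attr(img, "pitch") <- 1
  res <- segment_density(img, boundaries = c(0, 10, 30, 50))
  expect_equal(res$integrated_density[1], sum(img[1:10, ]))
  expect_equal(res$integrated_density[2], sum(img[11:30, ]))
  expect_equal(sum(res$integrated_density), sum(img))

  flat <- matrix(2, 30, 5)
  attr(flat, "pitch") <- 1
  eq <- segment_density(flat, c(0, 10, 20, 30))
  expect_true(all(eq$integrated_density == eq$integrated_density[1]))
  expect_error(segment_density(img, c(10, 5, 20)), "increasing")
})

test_that("mask-delimited densities conserve the total exactly", {
  set.seed(5)
  signal <- array(runif(6 * 8 * 10), c(6, 8, 10))
  mask_ch <- array(runif(6 * 8 * 10), c(6, 8, 10))
  md <- masked_density(signal, mask_ch, threshold_method = 0.5)
  expect_identical(md$inside$integrated_density +
                     md$outside$integrated_density, sum(signal))

  every <- masked_density(signal, array(1, dim(signal)), threshold_method = 0.5)
  expect_equal(every$inside$integrated_density, sum(signal))
  expect_equal(every$outside$n_pixels, 0L)

  # disjoint blobs: signal entirely outside the mask
  sig2 <- array(0, c(4, 4, 4)); sig2[1, 1, 1] <- 7
  msk2 <- array(0, c(4, 4, 4)); msk2[4, 4, 4] <- 1
  dj <- masked_density(sig2, msk2, threshold_method = 0.5)
  expect_equal(dj$inside$integrated_density, 0)
  expect_error(masked_density(sig2, array(1, c(2, 2, 2))), "shape")
})

test_that("a planted in-mask signal reduction is recovered", {
  set.seed(21)
  base <- array(100 + rnorm(20 * 12 * 12, sd = 2), c(20, 12, 12))
  mask_ch <- array(0, c(20, 12, 12))
  mask_ch[6:15, , ] <- 1
  signal <- base
  signal[6:15, , ] <- signal[6:15, , ] * 0.75   # 25% autonomous reduction
  md <- masked_density(signal, mask_ch, threshold_method = 0.5)
  ratio <- md$inside$mean_density / md$outside$mean_density
  expect_equal(ratio, 0.75, tolerance = 0.05)
})

test_that("normalisation to a reference rescales group means", {
  img <- matrix(4, 20, 20); attr(img, "pitch") <- 1
  rois <- roi_spec("node", c(5, 15), c(10, 10), 4)
  res <- integrated_density(img, rois)
  self_norm <- normalize_to_reference(res, res, label = "self")
  expect_equal(glance(self_norm)$mean_integrated_density, 1)
  expect_equal(attr(self_norm, "normalization_ref"), "self")

  half <- integrated_density(img / 2, rois)
  expect_equal(glance(normalize_to_reference(half, res))$mean_integrated_density,
               0.5)
  zero <- integrated_density(img * 0, rois)
  expect_error(normalize_to_reference(res, zero), "reference")
})

test_that("planted node enrichment is recovered from projections across seeds", {
  ratios <- vapply(1:10, function(s) {
    p <- quiet_params(dispersion_amp = 0, node_enrichment = 1.6,
                      noise_poisson = TRUE, seed = 100 + s)
    ph <- generate_phantom(p)
    img <- project_ventral(ph$volume)
    nodes <- ph$truth$node_positions
    internodes <- nodes + p$period / 2
    internodes <- internodes[internodes < dim(ph$volume)[1] * p$voxel_pitch]
    ml_mid <- dim(ph$volume)[3] * p$voxel_pitch / 2
    rois <- rbind(
      roi_spec("node", nodes, ml_mid, c(2 * p$node_halfwidth * 0.8, 20)),
      roi_spec("internode", internodes, ml_mid, c(2 * p$node_halfwidth * 0.8, 20)))
    gl <- glance(integrated_density(img, rois, pitch = p$voxel_pitch))
    gl$mean_integrated_density[gl$kind == "node"] /
      gl$mean_integrated_density[gl$kind == "internode"]
  }, numeric(1))
  expect_true(all(abs(ratios - 1.6) / 1.6 <= 0.10))
})
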