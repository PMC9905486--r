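test_that("spatial gradients match closed forms", {
  bl <- 0.5
  pos <- (seq_len(40) - 0.5) * bl
  lin <- node_trace(pos, 0.2 + 0.01 * pos, bin_length = bl)
  g <- spatial_gradient(lin)
  expect_true(all(abs(g$gradient - 0.01) < 1e-10))

  tri_v <- c(seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10))
  tri <- node_trace((seq_along(tri_v) - 0.5) * bl, tri_v / 2, bin_length = bl)
  gt <- spatial_gradient(tri)$gradient
  s <- 0.05 / bl
  expect_true(all(abs(gt[2:9] - s) < 1e-9))
  expect_true(all(abs(gt[13:20] + s) < 1e-9))

  # cosine of period P, amplitude A: max derivative ~ 2*pi*A/P
  P <- 28; A <- 0.3
  cosn <- cosine_trace(period = P, bin = 0.25, n = 400, amplitude = A)
  gmax <- max(spatial_gradient(cosn)$gradient)
  expect_equal(gmax, 2 * pi * A / P, tolerance = 0.05)
})

test_that("the r statistic obeys its formula identities and bounds", {
  expect_equal(asymmetry_r(c(-1, 0.5, 1, -0.2)), 0)          # max = |min|
  expect_equal(asymmetry_r(c(3, -1)), 1)
  expect_equal(asymmetry_r(c(1, -3)), -1)
  expect_true(is.na(asymmetry_r(c(1, 2, 3))))                # no negative limb
  expect_true(is.na(asymmetry_r(numeric(0))))

  set.seed(9)
  for (i in 1:50) {
    g <- rnorm(20)
    r <- asymmetry_r(g)
    if (!is.na(r)) {
      expect_lte(abs(r), 2)
      expect_equal(asymmetry_r(-g), -r)                      # mirror flips sign
    }
  }
})

test_that("degenerate resampling reproduces the mean profile's limb fits", {
  tr <- cosine_trace(period = 28, bin = 1.75, n = 64, phase = 0.875)
  tr$sd <- 0
  st <- resample_r(tr, n_reps = 20, seed = 4)
  expect_equal(length(st$r_samples), 20)
  expect_true(all(abs(st$r_samples - st$r_samples[1]) < 1e-12))
  expect_equal(st$r, 0, tolerance = 1e-8)   # symmetric cosine: zero r

  st2 <- resample_r(tr, n_reps = 20, seed = 4)
  expect_identical(st$r_samples, st2$r_samples)
  expect_error(resample_r(tr, n_reps = 1), "n_reps")
})

test_that("resampling under a symmetric profile centres r on zero", {
  # peak on a grid point and an even period in bins: exactly mirror-symmetric
  tr <- cosine_trace(period = 28, bin = 1.75, n = 64, phase = 0.875)
  tr$sd <- 0.05
  st <- resample_r(tr, n_reps = 400, seed = 11)
  se <- sd(st$r_samples) / sqrt(sum(is.finite(st$r_samples)))
  expect_lte(abs(st$r), 2 * se + 0.02)
})

test_that("steeper posterior descent yields negative r, and its mirror positive", {
  bl <- 0.5
  pos <- seq(0.25, 120, by = bl)
  phase <- pos %% 28
  steep_desc <- node_trace(pos, ifelse(phase < 9, 1 - 0.8 * phase / 9,
                                       0.2 + 0.8 * (phase - 9) / 19),
                           bin_length = bl)
  steep_desc$sd <- 0.02
  st <- resample_r(steep_desc, n_reps = 100, seed = 2)
  expect_lt(st$r, 0)

  mirrored <- node_trace(pos, rev(steep_desc$value), bin_length = bl)
  mirrored$sd <- 0.02
  st_m <- resample_r(mirrored, n_reps = 100, seed = 2)
  expect_gt(st_m$r, 0)
})

test_that("replicate-mean precision scales as one over root n_reps", {
  tr <- cosine_trace(period = 28, bin = 1.75, n = 64, phase = 0.875)
  tr$sd <- 0.05
  st100 <- resample_r(tr, n_reps = 100, seed = 13)
  st400 <- resample_r(tr, n_reps = 400, seed = 13)
  se <- function(st) sd(st$r_samples) / sqrt(sum(is.finite(st$r_samples)))
  expect_equal(se(st100) / se(st400), 2, tolerance = 0.35)
})

test_that("tests against zero behave at the extremes", {
  expect_equal(test_r_zero(rep(0, 50)), 1)
  pos_samples <- runif(500, 0.2, 1)
  expect_lt(test_r_zero(pos_samples, "mann_whitney"), 0.001)
  expect_lt(test_r_zero(pos_samples, "signed_rank"), 0.001)
})

test_that("the signed-rank test is calibrated and the mirror test is liberal", {
  # null: symmetric r distribution; 120 seeded runs at alpha = 0.05
  n_runs <- 120
  p_sr <- numeric(n_runs)
  p_mw <- numeric(n_runs)
  # grid-symmetric profile kept away from the [0, 1] clip: the null r
  # distribution is symmetric about zero
  tr <- cosine_trace(period = 28, bin = 1.75, n = 64, amplitude = 0.25,
                     level = 0.5, phase = 0.875)
  tr$sd <- 0.05
  for (k in seq_len(n_runs)) {
    st <- resample_r(tr, n_reps = 120, seed = 1000 + k)
    p_sr[k] <- test_r_zero(st, "signed_rank")
    p_mw[k] <- test_r_zero(st, "mann_whitney")
  }
  rate_sr <- mean(p_sr < 0.05)
  expect_gte(rate_sr, 0.0)
  expect_lte(rate_sr, 0.12)
  # the mirror-based Mann-Whitney reuses the same draws in both groups and
  # is anti-conservative by construction
  expect_gte(mean(p_mw < 0.05), rate_sr)
})
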