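const_matrix <- function(n, value = 0.5, bl = 1.65) {
  m <- matrix(value, n, n)
  diag(m) <- 1
  vncorr:::new_corr_matrix(m, bl, c("a", "a"), matrix(TRUE, n, n))
}

test_that("node detection finds planted banding and nothing in flat matrices", {
  expect_identical(detect_nodes(const_matrix(20)), integer(0))

  # planted cosine banding of period k bins: high-correlation bands where
  # both bins sit near a node (product structure, as in real matrices)
  n <- 48; k <- 12; bl <- 1.65
  ci <- 0.5 + 0.3 * cos(2 * pi * seq_len(n) / k)
  m <- outer(ci, ci)
  diag(m) <- 1
  cm <- vncorr:::new_corr_matrix(m, bl, c("a", "a"), matrix(TRUE, n, n))
  peaks <- detect_nodes(cm, min_prominence = 0.05, min_separation = 0.5 * k * bl)
  expect_gte(length(peaks), 3)
  expect_true(all(diff(peaks) == k))
})

test_that("trace extraction averages the three anchor rows and skips the diagonal", {
  ones <- const_matrix(6, value = 1)
  tr <- extract_trace(ones, 3)
  expect_true(all(tr$value == 1))

  # hand-built 5x5 case: rows 2,3,4 hold 0.2/0.4/0.6 at column 1
  m <- matrix(0.5, 5, 5); diag(m) <- 1
  m[2, 1] <- 0.2; m[3, 1] <- 0.4; m[4, 1] <- 0.6
  cm <- vncorr:::new_corr_matrix(m, 1, c("a", "a"), matrix(TRUE, 5, 5))
  tr <- extract_trace(cm, 3)
  expect_equal(tr$value[1], mean(c(0.2, 0.4, 0.6)))
  # at the anchor columns the diagonal entries (value 1) are excluded:
  # column 3 averages m[2,3] and m[4,3] only
  expect_equal(tr$value[3], mean(c(m[2, 3], m[4, 3])))
  expect_equal(tr$value[2], mean(c(m[3, 2], m[4, 2])))

  edge <- extract_trace(cm, 1)
  expect_true(attr(edge, "edge"))
  expect_equal(edge$value[4], mean(c(m[1, 4], m[2, 4])))
  expect_error(extract_trace(cm, 9), "outside")
})

test_that("alignment recovers planted integer shifts and is idempotent", {
  base <- cosine_trace(period = 28, n = 60)
  shift <- function(tr, s) {
    node_trace(tr$position + s * 1.65, tr$value, bin_length = 1.65)
  }
  traces <- list(base, shift(base, 2), shift(base, -1))
  aligned <- align_traces(traces, window = c(25, 57))
  expect_equal(attr(aligned[[2]], "shift_bins"), -2L)
  expect_equal(attr(aligned[[3]], "shift_bins"), 1L)

  again <- align_traces(aligned, window = c(25, 57))
  expect_true(all(vapply(again, function(t) attr(t, "shift_bins"), integer(1)) == 0L))

  expect_equal(align_traces(list(base))[[1]]$value, base$value)

  # antiphase periodic traces come back in phase: the shift equals half a
  # period modulo the (inherent) whole-period ambiguity
  anti <- cosine_trace(period = 28, n = 60, phase = 14)
  out <- align_traces(list(base, anti), window = c(20, 60))
  resid <- (attr(out[[2]], "shift_bins") * 1.65 + 14) %% 28
  expect_lte(min(resid, 28 - resid), 1.65)
  bounded <- align_traces(list(base, anti), window = c(20, 60), max_shift = 14)
  expect_lte(abs(abs(attr(bounded[[2]], "shift_bins")) - round(14 / 1.65)), 1)

  expect_error(align_traces(traces, window = c(500, 600)), "window")
})

test_that("trace averaging gives per-position means, sample sd and coverage", {
  base <- cosine_trace(n = 20)
  avg <- average_traces(list(base, base, base))
  expect_equal(avg$value, base$value)
  expect_true(all(avg$sd == 0))
  expect_true(all(avg$n == 3L))

  a <- node_trace(base$position, rep(0.2, 20), bin_length = 1.65)
  b <- node_trace(base$position, rep(0.6, 20), bin_length = 1.65)
  ab <- average_traces(list(a, b))
  expect_equal(ab$value, rep(0.4, 20))
  expect_equal(ab$sd, rep(sd(c(0.2, 0.6)), 20))
  expect_equal(round(ab$sd[1], 3), 0.283)

  # a position covered by one trace only has undefined sd
  c_short <- node_trace(base$position[1:10] - 2 * 1.65, rep(0.5, 10),
                        bin_length = 1.65)
  mix <- average_traces(list(a, c_short))
  expect_true(is.na(mix$sd[1]))
  expect_equal(mix$n[1], 1L)
})

test_that("internodal metrics recover period and minimum offset of known profiles", {
  # pure cosine, period 28: symmetric internode, minimum at half period
  tr <- cosine_trace(period = 28, n = 80)
  m <- internodal_metrics(tr)
  expect_equal(m$mean_internodal_distance, 28, tolerance = 0.1)
  expect_equal(mean(m$node_to_min_offsets), 14, tolerance = 0.5)
  expect_equal(m$internodal_distances, diff(m$node_positions))

  # asymmetric sawtooth-like profile with the minimum 9 μm after each peak
  bl <- 0.5
  pos <- seq(0.25, 120, by = bl)
  phase <- pos %% 28
  v <- ifelse(phase < 9, 1 - 0.8 * phase / 9, 0.2 + 0.8 * (phase - 9) / 19)
  saw <- node_trace(pos, v, bin_length = bl)
  ms <- internodal_metrics(saw)
  expect_equal(mean(ms$node_to_min_offsets), 9, tolerance = 0.75)
  expect_equal(ms$mean_internodal_distance, 28, tolerance = 0.6)

  tidy_ms <- tidy(ms)
  expect_equal(nrow(tidy_ms), ms$n_nodes - 1L)
  expect_equal(glance(ms)$mean_internodal_distance, ms$mean_internodal_distance)

  expect_error(internodal_metrics(cosine_trace(period = 200, n = 30)),
               "insufficient nodes")
})

test_that("noiseless phantoms return the planted period within one bin", {
  for (period in c(25, 28, 33)) {
    # 0.825 um voxels (two planes per 1.65 um bin exactly); four segments so
    # interior nodes outweigh the two edge ones
    p <- quiet_params(period = period, seed = 3, voxel_pitch = 0.825,
                      cross_section = c(32, 22), n_segments = 4)
    arch <- node_architecture(generate_phantom(p)$volume, bin_length = 1.65,
                              min_separation = period / 2)
    expect_equal(arch$slabs$bin_length, 1.65)
    expect_lte(abs(arch$metrics$mean_internodal_distance - period), 1.65)
  }
})

test_that("one node per segment is detected across seeds", {
  counts <- vapply(1:10, function(s) {
    p <- quiet_params(voxel_pitch = 0.825, cross_section = c(32, 22), seed = s,
                      noise_gaussian_sd = 2, noise_poisson = TRUE)
    ph <- generate_phantom(p)
    slabs <- bin_and_project(ph$volume, 1.65)
    m <- self_correlation_matrix(slabs)
    length(detect_nodes(m))
  }, integer(1))
  expect_true(all(counts == 3L))
})
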