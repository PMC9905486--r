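# run expr with a private, seeded RNG stream, restoring the caller's state
with_phantom_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parameters of the synthetic nerve-cord phantom
#'
#' Describes a segmentally periodic arrangement of longitudinal axon fascicles:
#' per hemiside, three compact fasciculated units (medial, intermediate,
#' lateral) run along AP, compact at evenly spaced 3D nodes and dispersing
#' between them. The internodal dispersion envelope rises from each node to a
#' maximum and decays towards the next node; `dispersion_asymmetry` blends the
#' position of that maximum between the internode midpoint (0, symmetric) and
#' `min_offset` posterior to the node (1). Intensity is multiplied by
#' `node_enrichment` inside node windows, mimicking node-enriched adhesion
#' signal. A Gaussian PSF blur, then Poisson photon noise, then Gaussian read
#' noise are applied, in that order. One hemiside is generated and mirrored
#' about the ML midline.
#'
#' @param n_segments number of segments (one node each).
#' @param period node-to-node AP spacing, μm.
#' @param min_offset AP distance from a node to the target dispersion maximum
#'   (the expected correlation minimum), μm, measured posteriorly.
#' @param voxel_pitch isotropic voxel size, μm.
#' @param cross_section integer `(ML, DV)` extents in voxels; default derived
#'   from a 26 x 18 μm field (ML forced even so mirroring is exact).
#' @param fascicle_positions list of `(ml, dv)` μm anchor coordinates per
#'   hemiside; `ml` measured from the midline, `dv` from the ventral face.
#' @param fascicle_radius Gaussian tube radius, μm.
#' @param dispersion_amp peak lateral wander of fascicles between nodes, μm.
#'   Calibrated so the internodal correlation minimum stays above its
#'   saturation floor (about twice the effective tube width); larger values
#'   reproduce the mutant-like fading of the minima.
#' @param dispersion_asymmetry in `[0, 1]`; see Description.
#' @param node_enrichment intensity multiplier (>= 1) inside node windows.
#' @param node_halfwidth half-width of the node window, μm.
#' @param psf_sigma PSF standard deviation, μm.
#' @param noise_gaussian_sd additive Gaussian noise sd, intensity units
#'   (fascicle peak amplitude is 100).
#' @param noise_poisson logical; apply Poisson photon noise.
#' @param lateral_dropout probability per internode that the lateral fascicle
#'   is absent (mutant-like incompleteness), in `[0, 1]`.
#' @param seed integer RNG seed; identical parameters including the seed give
#'   a bit-identical volume.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(n_segments = 6L,
                           period = 28,
                           min_offset = 9,
                           voxel_pitch = 0.55,
                           cross_section = NULL,
                           fascicle_positions = list(c(2.2, 11), c(5.5, 9), c(8.8, 7)),
                           fascicle_radius = 0.9,
                           dispersion_amp = 2,
                           dispersion_asymmetry = 1,
                           node_enrichment = 1.5,
                           node_halfwidth = 2.5,
                           psf_sigma = 0.4,
                           noise_gaussian_sd = 2,
                           noise_poisson = TRUE,
                           lateral_dropout = 0,
                           seed = 1L) {
  if (!is.numeric(voxel_pitch) || length(voxel_pitch) != 1L || voxel_pitch <= 0) {
    abort("invalid phantom parameter `voxel_pitch`: must be > 0")
  }
  if (is.null(cross_section)) {
    ml <- round(26 / voxel_pitch)
    cross_section <- c(ml + ml %% 2L, round(18 / voxel_pitch))
  }
  p <- list(
    n_segments = as.integer(n_segments), period = period,
    min_offset = min_offset, voxel_pitch = voxel_pitch,
    cross_section = as.integer(cross_section),
    fascicle_positions = fascicle_positions,
    fascicle_radius = fascicle_radius, dispersion_amp = dispersion_amp,
    dispersion_asymmetry = dispersion_asymmetry,
    node_enrichment = node_enrichment, node_halfwidth = node_halfwidth,
    psf_sigma = psf_sigma, noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson = isTRUE(noise_poisson), lateral_dropout = lateral_dropout,
    seed = as.integer(seed)
  )
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  bad <- function(field, why) {
    abort(paste0("invalid phantom parameter `", field, "`: ", why))
  }
  if (p$n_segments < 1L) bad("n_segments", "must be >= 1")
  if (!(p$period > 2 * p$node_halfwidth)) {
    bad("period", "must exceed twice node_halfwidth")
  }
  if (!(p$min_offset > 0 && p$min_offset < p$period)) {
    bad("min_offset", "must lie in (0, period)")
  }
  for (f in c("voxel_pitch", "fascicle_radius")) {
    if (!(p[[f]] > 0)) bad(f, "must be > 0")
  }
  for (f in c("dispersion_amp", "node_halfwidth", "psf_sigma",
              "noise_gaussian_sd", "min_offset", "period")) {
    if (p[[f]] < 0) bad(f, "must be >= 0")
  }
  for (f in c("dispersion_asymmetry", "lateral_dropout")) {
    if (p[[f]] < 0 || p[[f]] > 1) bad(f, "must lie in [0, 1]")
  }
  if (p$node_enrichment < 1) bad("node_enrichment", "must be >= 1")
  if (length(p$cross_section) != 2L || any(p$cross_section < 4L)) {
    bad("cross_section", "must be two extents of >= 4 voxels (ML, DV)")
  }
  if (p$cross_section[1L] %% 2L != 0L) {
    bad("cross_section", "ML extent must be even so hemiside mirroring is exact")
  }
  peak <- envelope_peak(p)
  if (!(peak > 0 && peak < p$period)) {
    bad("min_offset", "dispersion maximum must fall between successive nodes")
  }
  invisible(p)
}

#' Preset phantom parameter sets
#'
#' `wildtype` plants the wild-type architecture: nodes 28 μm apart with the
#' internodal correlation minimum 9 μm posterior to the node. `puc_like`
#' emulates the defasciculated mutant class: 33 μm spacing, raised dispersion,
#' noisier sections and stochastic loss of the lateral fascicle between nodes.
#' `zfh1_like` plants 33 μm spacing with a symmetric, flattened internodal
#' dispersion profile.
#'
#' @param name one of `"wildtype"`, `"puc_like"`, `"zfh1_like"`.
#' @param ... overrides passed on to [phantom_params()].
#' @return A [phantom_params()] object.
#' @export
phantom_preset <- function(name, ...) {
  presets <- c("wildtype", "puc_like", "zfh1_like")
  if (length(name) != 1L || !name %in% presets) {
    abort(paste0("unknown preset '", name, "'; valid presets: ",
                 paste(presets, collapse = ", ")))
  }
  base <- switch(name,
    wildtype = list(period = 28, min_offset = 9, dispersion_asymmetry = 1,
                    dispersion_amp = 2, lateral_dropout = 0,
                    noise_gaussian_sd = 2),
    puc_like = list(period = 33, min_offset = 9, dispersion_asymmetry = 1,
                    dispersion_amp = 4.5, lateral_dropout = 0.3,
                    noise_gaussian_sd = 4),
    zfh1_like = list(period = 33, min_offset = 16.5, dispersion_asymmetry = 0,
                     dispersion_amp = 2, lateral_dropout = 0,
                     noise_gaussian_sd = 4)
  )
  do.call(phantom_params, utils::modifyList(base, list(...)))
}

# AP position of the dispersion maximum, relative to the preceding node
envelope_peak <- function(p) {
  p$dispersion_asymmetry * p$min_offset +
    (1 - p$dispersion_asymmetry) * p$period / 2
}

# piecewise-linear (triangular) internodal dispersion envelope at AP offsets
# phi in [0, period) after a node: zero exactly at the node (the point of
# maximal compaction), rising linearly to 1 at the peak, then decaying
# linearly to the next node. The kinked extrema keep the correlation maxima
# at the nodes and the minimum pinned at the peak position; the node window
# (node_halfwidth) gates only the intensity enrichment.
dispersion_envelope <- function(phi, p) {
  peak <- envelope_peak(p)
  e <- numeric(length(phi))
  rise <- phi > 0 & phi <= peak
  fall <- phi > peak & phi < p$period
  e[rise] <- phi[rise] / peak
  e[fall] <- (p$period - phi[fall]) / (p$period - peak)
  e
}

# separable Gaussian blur of a 3D array, sigma in voxels (scalar)
gaussian_blur3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, seq_along(d)[-axis])
    m <- matrix(aperm(a, perm), nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    w <- numeric(n)
    for (t in seq(-r, r)) {
      src <- seq_len(n) + t
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[t + r + 1L] * m[src[ok], , drop = FALSE]
      w[ok] <- w[ok] + k[t + r + 1L]
    }
    out <- out / w
    aperm(array(out, d[perm]), order(perm))
  }
  for (axis in 1:3) x <- blur_axis(x, axis)
  x
}

#' Generate a synthetic nerve-cord stack with known ground truth
#'
#' Renders the fascicle architecture described by a [phantom_params()] object
#' into a calibrated isotropic volume: smooth per-fascicle wander curves
#' (independent random directions per fascicle and internode, scaled by the
#' dispersion envelope) rasterised as Gaussian tubes, node-window intensity
#' enrichment, PSF blur, then Poisson and Gaussian noise. Deterministic for a
#' fixed parameter set including the seed.
#'
#' @param params a [phantom_params()].
#' @return A list with elements `volume` (a [vnc_volume()], AP length
#'   `n_segments * period`) and `truth` (a `phantom_truth` list of
#'   `node_positions`, `segment_boundaries`, `expected_min_positions` — all μm —
#'   and `enrichment_factor`).
#' @examples
#' ph <- generate_phantom(phantom_params(n_segments = 2, voxel_pitch = 1.1))
#' ph$truth$node_positions
#' @export
generate_phantom <- function(params) {
  p <- validate_phantom_params(params)
  pitch <- p$voxel_pitch
  n_ap <- round(p$n_segments * p$period / pitch)
  w_ml <- p$cross_section[1L]
  n_dv <- p$cross_section[2L]
  half_w <- ceiling(w_ml / 2)
  z_um <- (seq_len(n_ap) - 0.5) * pitch
  dv_um <- (seq_len(n_dv) - 0.5) * pitch
  ml_um <- (seq_len(half_w) - 0.5) * pitch   # left hemiside, midline at half_w*pitch
  midline <- (w_ml / 2) * pitch

  nodes <- (seq_len(p$n_segments) - 0.5) * p$period
  phi <- (z_um - nodes[1L]) %% p$period            # offset after preceding node
  slot <- floor((z_um - nodes[1L]) / p$period)     # internode slot index
  env <- dispersion_envelope(phi, p) * p$dispersion_amp
  n_slots <- max(slot) - min(slot) + 1L
  slot_i <- slot - min(slot) + 1L

  n_f <- length(p$fascicle_positions)
  # Wander directions form a zero-sum triad: per internode one random
  # orientation, with the fascicles 2*pi/n_f apart, plus a common smooth
  # rotation field (knots every ~3 um). Displacement magnitudes equal the
  # envelope exactly and the vector sum is zero, so rigid registration cannot
  # cancel the dispersion and the correlation minimum stays pinned at the
  # envelope peak, while sections decorrelate within an internode.
  rot_knots <- seq(-p$period, p$n_segments * p$period + p$period, by = 3)
  vol <- with_phantom_rng(p$seed, {
    theta0 <- runif(n_slots, 0, 2 * pi)
    rot_field <- stats::approx(rot_knots, runif(length(rot_knots), -pi / 2, pi / 2),
                               xout = z_um)$y
    dropped <- runif(n_slots) < p$lateral_dropout
    half <- array(0, c(n_ap, n_dv, half_w))
    amp <- 100
    for (f in seq_len(n_f)) {
      anchor_ml <- midline - p$fascicle_positions[[f]][1L]
      anchor_dv <- p$fascicle_positions[[f]][2L]
      th <- theta0[slot_i] + (f - 1) * 2 * pi / n_f + rot_field
      c_ml <- anchor_ml + env * cos(th)
      c_dv <- anchor_dv + env * sin(th)
      a_z <- rep(amp, n_ap)
      if (f == n_f && any(dropped)) {
        # lateral fascicle absent across dropped internode interiors
        interior <- phi > p$node_halfwidth & phi < p$period - p$node_halfwidth
        a_z[dropped[slot_i] & interior] <- 0
      }
      s2 <- 2 * p$fascicle_radius^2
      for (z in seq_len(n_ap)) {
        if (a_z[z] == 0) next
        g <- outer((dv_um - c_dv[z])^2, (ml_um - c_ml[z])^2, "+")
        half[z, , ] <- half[z, , ] + a_z[z] * exp(-g / s2)
      }
    }
    # node-window intensity enrichment
    in_node <- phi <= p$node_halfwidth | phi >= p$period - p$node_halfwidth
    half <- half * (1 + (p$node_enrichment - 1) * in_node)
    # mirror the left hemiside about the ML midline (w_ml is even)
    full <- array(0, c(n_ap, n_dv, w_ml))
    full[, , seq_len(half_w)] <- half
    full[, , seq.int(half_w + 1L, w_ml)] <- half[, , seq.int(half_w, 1L)]
    full <- gaussian_blur3(full, p$psf_sigma / pitch)
    if (p$noise_poisson) {
      full <- array(rpois(length(full), lambda = full), dim(full))
    }
    if (p$noise_gaussian_sd > 0) {
      full <- full + rnorm(length(full), sd = p$noise_gaussian_sd)
    }
    pmax(full, 0)
  })

  truth <- structure(
    list(node_positions = nodes,
         segment_boundaries = seq(0, p$n_segments) * p$period,
         expected_min_positions = nodes + envelope_peak(p),
         enrichment_factor = p$node_enrichment,
         params = p),
    class = "phantom_truth"
  )
  list(volume = vnc_volume(vol, pitch), truth = truth)
}

#' Analytic expected correlation trace of a phantom
#'
#' Noiseless oracle for the node-anchored correlation profile: the correlation
#' of two Gaussian tubes of effective width `sqrt(fascicle_radius^2 +
#' psf_sigma^2)` displaced by `d` is `exp(-d^2 / (4 sigma^2))`, so the expected
#' profile is that function of the dispersion envelope. Maximal (1) at nodes,
#' minimal at the envelope peak, periodic with the segmental period.
#'
#' @param params a [phantom_params()].
#' @return A [node_trace()] tibble over the full AP extent at the voxel pitch.
#' @export
expected_trace <- function(params) {
  p <- validate_phantom_params(params)
  n_ap <- round(p$n_segments * p$period / p$voxel_pitch)
  z_um <- (seq_len(n_ap) - 0.5) * p$voxel_pitch
  phi <- (z_um - p$period / 2) %% p$period
  env <- dispersion_envelope(phi, p) * p$dispersion_amp
  s2 <- p$fascicle_radius^2 + p$psf_sigma^2
  node_trace(position = z_um, value = exp(-env^2 / (4 * s2)),
             bin_length = p$voxel_pitch, reference_bin = NA_integer_)
}
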