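#' Rigid in-plane transform
#'
#' A translation (DV, ML, in μm) plus a rotation (radians, counter-clockwise
#' about the section centre) mapping moving-image coordinates into the fixed
#' frame: `fixed = R(rotation) (moving - centre) + centre + translation`.
#'
#' @param translation numeric length-2, `(DV, ML)` in μm.
#' @param rotation rotation angle in radians.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(translation = c(0, 0), rotation = 0) {
  stopifnot(length(translation) == 2L, is.finite(rotation))
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.4g, %.4g) μm, rot = %.4g rad\n",
              x$translation[1], x$translation[2], x$rotation))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform` (same centre convention).
#' @export
invert_transform <- function(transform) {
  th <- -transform$rotation
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform(as.numeric(-rot %*% transform$translation), th)
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform()]s; the result applies `b` first, then `a`.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  th <- a$rotation
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform(as.numeric(rot %*% b$translation) + a$translation,
                  a$rotation + b$rotation)
}

#' Registration options
#'
#' Controls for pairwise rigid registration: a multimodal (mutual-information)
#' metric, convergence tolerance `1e-6` and at most 500 iterations by default,
#' matching the reference pipeline's optimiser settings.
#'
#' @param metric similarity metric; only `"mutual_information"` is available.
#' @param tolerance relative convergence tolerance of the optimiser.
#' @param max_iterations iteration cap; on non-convergence the best transform
#'   so far is returned with a `converged = FALSE` flag, never an error.
#' @param allow_rotation optimise the rotation angle as well as translation.
#' @param min_overlap_fraction minimum fraction of pixels that must remain in
#'   field after resampling for a correlation score to be defined.
#' @param mi_bins histogram bins per marginal for the metric.
#' @param seed integer seed applied before optimisation (the optimiser itself
#'   is deterministic; the seed pins any future stochastic component).
#' @return A `reg_options` list.
#' @export
reg_options <- function(metric = "mutual_information",
                        tolerance = 1e-6,
                        max_iterations = 500L,
                        allow_rotation = TRUE,
                        min_overlap_fraction = 0.5,
                        mi_bins = 32L,
                        seed = 1L) {
  metric <- match.arg(metric, "mutual_information")
  stopifnot(tolerance > 0, max_iterations >= 1, mi_bins >= 4,
            min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  structure(list(metric = metric, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 allow_rotation = isTRUE(allow_rotation),
                 min_overlap_fraction = min_overlap_fraction,
                 mi_bins = as.integer(mi_bins), seed = as.integer(seed)),
            class = "reg_options")
}

section_center <- function(img) (dim(img) + 1) / 2 - 1  # 0-based voxel centre

# resample `moving` into the fixed frame under `transform` (μm / radians);
# returns list(values, mask) in voxel space
resample_moving <- function(moving, transform, pitch) {
  ctr <- section_center(moving)
  cpp_resample_rigid(moving,
                     transform$translation[1] / pitch,
                     transform$translation[2] / pitch,
                     transform$rotation, ctr[1], ctr[2])
}

#' Centre-of-mass prealignment
#'
#' Translation-only transform mapping the intensity centroid of `moving` onto
#' that of `fixed`, maximising initial overlap before metric optimisation.
#'
#' @param fixed,moving 2D numeric matrices (DV x ML) of equal orientation.
#' @param pitch in-plane pixel size in μm.
#' @return A [rigid_transform()] with zero rotation.
#' @export
com_prealign <- function(fixed, moving, pitch = 1) {
  centroid <- function(img) {
    tot <- sum(img)
    if (!is.finite(tot) || tot <= 0) abort("cannot prealign a zero-intensity image")
    c(sum(row(img) * img), sum(col(img) * img)) / tot
  }
  rigid_transform((centroid(fixed) - centroid(moving)) * pitch, 0)
}

#' Rigid registration of two transverse sections
#'
#' Prealigns the centres of mass, then locally optimises the rigid transform
#' (translation, optionally rotation) under a mutual-information metric with
#' Nelder-Mead, using the configured tolerance and iteration cap. Of the
#' prealigned and optimised candidates, the one with the higher
#' post-registration correlation score is returned, so registration never
#' scores below prealignment.
#'
#' @param fixed,moving 2D numeric matrices of identical shape.
#' @param opts a [reg_options()].
#' @param pitch in-plane pixel size in μm.
#' @return A [rigid_transform()] with attributes `converged` (logical) and
#'   `metric_value` (final mutual information, nats).
#' @export
register_rigid <- function(fixed, moving, opts = reg_options(), pitch = 1) {
  stopifnot(identical(dim(fixed), dim(moving)))
  pre <- com_prealign(fixed, moving, pitch)
  neg_mi <- function(par) {
    tr <- rigid_transform(par[1:2], if (length(par) > 2L) par[3] else 0)
    rs <- resample_moving(moving, tr, pitch)
    -cpp_mutual_information(fixed, rs$values, rs$mask, opts$mi_bins)
  }
  th0 <- 0
  if (opts$allow_rotation) {
    # the histogram MI surface is locally flat in the angle; seed the simplex
    # from a coarse sweep (±20 degrees) at the CoM translation
    sweep <- seq(-0.35, 0.35, by = 0.035)
    th0 <- sweep[which.min(vapply(sweep, function(th) {
      neg_mi(c(pre$translation, th))
    }, numeric(1)))]
  }
  par0 <- c(pre$translation, if (opts$allow_rotation) th0)
  # scale the simplex to one pixel of translation / ~3 degrees of rotation
  scales <- c(pitch, pitch, if (opts$allow_rotation) 0.05)
  set.seed(opts$seed)
  fit <- optim(par0, neg_mi, method = "Nelder-Mead",
               control = list(reltol = opts$tolerance,
                              maxit = opts$max_iterations,
                              parscale = scales))
  opt <- rigid_transform(fit$par[1:2],
                         if (opts$allow_rotation) fit$par[3] else 0)
  score_of <- function(tr) {
    s <- correlation_score(fixed, moving, tr, pitch = pitch,
                           min_overlap_fraction = 0)
    if (is.na(s)) -Inf else s
  }
  best <- if (score_of(opt) >= score_of(pre)) opt else pre
  attr(best, "converged") <- fit$convergence == 0L
  attr(best, "metric_value") <- -fit$value
  best
}

#' Post-registration correlation score
#'
#' Pearson correlation between the fixed section and the rigidly resampled
#' moving section, computed over the in-field overlap only (out-of-field
#' pixels are excluded, not wrapped or zero-scored) and clipped below at 0 to
#' match the 0-1 scale of the correlation matrices. Returns `NA` (a missing
#' value, not an error) when the overlap falls below `min_overlap_fraction`
#' or the overlap has zero variance.
#'
#' @param fixed,moving 2D numeric matrices of identical shape.
#' @param transform a [rigid_transform()] mapping moving into the fixed frame.
#' @param pitch in-plane pixel size in μm.
#' @param min_overlap_fraction minimum in-field fraction for a defined score.
#' @return A score in `[0, 1]`, or `NA_real_`.
#' @export
correlation_score <- function(fixed, moving, transform = rigid_transform(),
                              pitch = 1, min_overlap_fraction = 0.5) {
  stopifnot(identical(dim(fixed), dim(moving)))
  rs <- resample_moving(moving, transform, pitch)
  if (mean(rs$mask) < min_overlap_fraction) return(NA_real_)
  r <- cpp_masked_pearson(fixed, rs$values, rs$mask)
  if (is.na(r)) return(NA_real_)
  max(r, 0)
}
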