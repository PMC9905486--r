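#' Ventral-view projection of a volume
#'
#' Maximum-intensity projection along DV, the standard view for ROI-based
#' fluorescence quantification: rows are AP, columns ML.
#'
#' @param volume a [vnc_volume()] (isotropic in AP/ML for a calibrated view).
#' @param channel channel to project.
#' @return A numeric matrix (AP x ML) with a `pitch` attribute (μm).
#' @export
project_ventral <- function(volume, channel = 1L) {
  x <- get_channel(volume, channel)$intensities
  out <- apply(x, c(1, 3), max)
  attr(out, "pitch") <- unname(volume$pitch[["ap"]])
  out
}

#' Fixed-size quantification ROIs
#'
#' Builds the ROI table consumed by [integrated_density()]: one fixed-size
#' square per supplied centre. ROIs are axis-aligned rectangles given by
#' centre (AP, ML) and size (AP, ML), all in μm.
#'
#' @param kind character label per ROI (`"node"`, `"internode"`, `"segment"`,
#'   ...).
#' @param center_ap,center_ml ROI centres, μm.
#' @param size length-2 `(AP, ML)` ROI size in μm (recycled scalar allowed);
#'   every ROI of one analysis shares it.
#' @return A tibble with columns `kind`, `center_ap`, `center_ml`, `w_ap`,
#'   `w_ml`.
#' @export
roi_spec <- function(kind, center_ap, center_ml, size) {
  if (length(size) == 1L) size <- c(size, size)
  tibble::tibble(kind = kind, center_ap = center_ap, center_ml = center_ml,
                 w_ap = size[1], w_ml = size[2])
}

roi_pixels <- function(image, pitch, lo_ap, hi_ap, lo_ml, hi_ml, label) {
  d <- dim(image)
  if (lo_ap < -1e-9 || lo_ml < -1e-9 ||
      hi_ap > d[1] * pitch + 1e-9 || hi_ml > d[2] * pitch + 1e-9) {
    abort(paste0("ROI '", label, "' falls outside the image"))
  }
  # pixels whose centres lie in the half-open window (adjacent ROIs tile
  # without double counting)
  ap_c <- (seq_len(d[1]) - 0.5) * pitch
  ml_c <- (seq_len(d[2]) - 0.5) * pitch
  list(rows = which(ap_c >= lo_ap & ap_c < hi_ap),
       cols = which(ml_c >= lo_ml & ml_c < hi_ml))
}

new_density_result <- function(per_roi, pitch, normalization_ref = NA_character_) {
  out <- per_roi
  class(out) <- c("density_result", class(tibble::tibble()))
  attr(out, "pitch") <- pitch
  attr(out, "normalization_ref") <- normalization_ref
  out
}

#' Integrated density over fixed-size ROIs
#'
#' The Fiji "IntDen" convention: per ROI, the sum of pixel intensities times
#' the pixel area; the Average Integrated Density of a group (nodes,
#' internodes, ...) is the mean of its ROIs' integrated densities, reported
#' with the sample standard deviation by [glance.density_result()].
#'
#' @param image 2D numeric matrix (AP x ML), e.g. from [project_ventral()].
#' @param rois ROI table from [roi_spec()]; an empty table gives an empty
#'   result.
#' @param pitch pixel size in μm; defaults to the image's `pitch` attribute.
#' @return A `density_result` tibble: one row per ROI with `kind`,
#'   `integrated_density` (intensity x μm²), `mean_density`, `n_pixels`.
#' @export
integrated_density <- function(image, rois, pitch = attr(image, "pitch")) {
  if (is.null(pitch)) abort("`pitch` required (μm per pixel)")
  px_area <- pitch^2
  rows <- lapply(seq_len(nrow(rois)), function(k) {
    r <- rois[k, ]
    px <- roi_pixels(image, pitch,
                     r$center_ap - r$w_ap / 2, r$center_ap + r$w_ap / 2,
                     r$center_ml - r$w_ml / 2, r$center_ml + r$w_ml / 2,
                     paste0(r$kind, " #", k))
    vals <- image[px$rows, px$cols]
    tibble::tibble(kind = r$kind, center_ap = r$center_ap,
                   center_ml = r$center_ml,
                   integrated_density = sum(vals) * px_area,
                   mean_density = if (length(vals)) mean(vals) else NA_real_,
                   n_pixels = length(vals))
  })
  per_roi <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(kind = character(), center_ap = numeric(),
                   center_ml = numeric(), integrated_density = numeric(),
                   mean_density = numeric(), n_pixels = integer())
  new_density_result(per_roi, pitch)
}

#' Segment-wise integrated density
#'
#' One ROI per span between successive AP boundaries, covering the full ML
#' width — the whole-segment quantification mode.
#'
#' @param image 2D numeric matrix (AP x ML).
#' @param boundaries strictly increasing AP positions in μm (at least 2).
#' @param pitch pixel size in μm.
#' @return A `density_result` with one `"segment"` row per span.
#' @export
segment_density <- function(image, boundaries, pitch = attr(image, "pitch")) {
  if (length(boundaries) < 2L || is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be at least 2 strictly increasing AP positions")
  }
  if (is.null(pitch)) abort("`pitch` required (μm per pixel)")
  ml_extent <- ncol(image) * pitch
  rows <- lapply(seq_len(length(boundaries) - 1L), function(k) {
    px <- roi_pixels(image, pitch, boundaries[k], boundaries[k + 1L],
                     0, ml_extent, paste0("segment #", k))
    vals <- image[px$rows, px$cols]
    tibble::tibble(kind = "segment",
                   center_ap = mean(boundaries[k:(k + 1L)]),
                   center_ml = ml_extent / 2,
                   integrated_density = sum(vals) * pitch^2,
                   mean_density = if (length(vals)) mean(vals) else NA_real_,
                   n_pixels = length(vals))
  })
  new_density_result(dplyr::bind_rows(rows), pitch)
}

#' Mask-delimited quantification
#'
#' Thresholds a co-registered mask channel (e.g. a driver-line GFP signal)
#' into a binary mask and quantifies the signal channel inside versus outside
#' it — the autonomous/non-autonomous decomposition. Inside and outside
#' integrated densities sum exactly to the whole-image total.
#'
#' @param signal 2D or 3D numeric array of the quantified channel.
#' @param mask_channel numeric array of the same shape, thresholded into the
#'   mask.
#' @param threshold_method `"otsu"` (default) or a fixed numeric threshold.
#' @param pitch pixel size in μm (area/volume element is `pitch^ndim`).
#' @return A list with `density_result`s `inside` and `outside` (one row
#'   each) and the logical `mask`.
#' @export
masked_density <- function(signal, mask_channel, threshold_method = "otsu",
                           pitch = 1) {
  if (!identical(dim(signal), dim(mask_channel))) {
    abort("`signal` and `mask_channel` must be co-registered (same shape)")
  }
  thr <- resolve_threshold(mask_channel, threshold_method)
  mask <- mask_channel > thr
  el <- pitch^length(dim(signal))
  one <- function(kind, vals) {
    new_density_result(
      tibble::tibble(kind = kind, center_ap = NA_real_, center_ml = NA_real_,
                     integrated_density = sum(vals) * el,
                     mean_density = if (length(vals)) mean(vals) else NA_real_,
                     n_pixels = length(vals)),
      pitch)
  }
  list(inside = one("inside", signal[mask]),
       outside = one("outside", signal[!mask]),
       mask = mask)
}

#' Normalise densities to a reference group
#'
#' Divides every density by the mean integrated density of the reference
#' result (e.g. a control genotype), recording the reference label.
#'
#' @param result,reference `density_result`s.
#' @param label recorded as the normalisation reference name.
#' @return The rescaled `density_result`.
#' @export
normalize_to_reference <- function(result, reference, label = "reference") {
  ref_mean <- mean(reference$integrated_density)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    abort("reference mean integrated density must be > 0")
  }
  out <- result
  out$integrated_density <- out$integrated_density / ref_mean
  out$mean_density <- out$mean_density / ref_mean
  attr(out, "normalization_ref") <- label
  out
}

#' Group summary of a density result
#'
#' @param x a `density_result`.
#' @param ... unused.
#' @return A tibble with one row per ROI kind: `kind`, `n`,
#'   `mean_integrated_density` (the Average Integrated Density),
#'   `sd_integrated_density`, `mean_density`.
#' @method glance density_result
#' @export
glance.density_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$kind),
    n = dplyr::n(),
    mean_integrated_density = mean(.data$integrated_density),
    sd_integrated_density = sd(.data$integrated_density),
    mean_density = mean(.data$mean_density),
    .groups = "drop")
}
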