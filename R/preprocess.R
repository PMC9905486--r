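# linear interpolation of one array axis onto a new voxel grid of pitch
# `target`, preserving the physical extent (voxel centres at (i - 0.5) * pitch)
interp_axis <- function(arr, axis, old_pitch, target) {
  d <- dim(arr)
  n_old <- d[axis]
  extent <- n_old * old_pitch
  n_new <- max(1L, round(extent / target))
  if (n_new == n_old && isTRUE(all.equal(old_pitch, target))) return(arr)
  x_old <- (seq_len(n_old) - 0.5) * old_pitch
  x_new <- (seq_len(n_new) - 0.5) * target
  i0 <- findInterval(x_new, x_old, all.inside = TRUE)
  w1 <- (x_new - x_old[i0]) / old_pitch
  w1 <- pmin(pmax(w1, 0), 1)  # clamp: constant extrapolation at the faces
  perm <- c(axis, seq_along(d)[-axis])
  m <- matrix(aperm(arr, perm), nrow = n_old)
  out <- m[i0, , drop = FALSE] * (1 - w1) + m[pmin(i0 + 1L, n_old), , drop = FALSE] * w1
  out <- array(out, c(n_new, d[-axis]))
  aperm(out, order(perm))
}

#' Rescale a volume to isotropic voxels
#'
#' Linearly interpolates each axis onto a grid of equal pitch, preserving the
#' physical extent to within one voxel. Confocal stacks are typically coarser
#' along the optical (AP, after reslicing) axis; downstream stages require
#' isotropy so that AP bins and transverse pixels share one length scale.
#'
#' @param volume a [vnc_volume()].
#' @param target_pitch desired isotropic voxel size in μm; default the finest
#'   of the native pitches.
#' @return A [vnc_volume()] with all three pitches equal to `target_pitch`.
#' @export
rescale_isotropic <- function(volume, target_pitch = NULL) {
  stopifnot(inherits(volume, "vnc_volume"))
  if (is.null(target_pitch)) target_pitch <- min(volume$pitch)
  if (!is.numeric(target_pitch) || target_pitch <= 0) {
    abort("`target_pitch` must be a positive length in μm")
  }
  x <- volume$intensities
  for (axis in 1:3) x <- interp_axis(x, axis, volume$pitch[axis], target_pitch)
  vnc_volume(x, rep(target_pitch, 3), volume$channels)
}

is_isotropic <- function(volume, tol = 1e-8) {
  diff(range(volume$pitch)) <= tol * mean(volume$pitch)
}

#' Crop a volume to the nerve cord
#'
#' With an explicit `box`, crops to those voxel index ranges. Without one, the
#' crop is automatic: the bounding box of voxels above the Otsu threshold of
#' the reference channel, padded by `margin` voxels and clamped to the volume.
#'
#' @param volume a [vnc_volume()].
#' @param box optional 3x2 integer matrix of 1-based inclusive index ranges,
#'   rows in (AP, DV, ML) order.
#' @param margin padding in voxels around the automatic bounding box.
#' @param channel reference channel for the automatic threshold.
#' @return The cropped [vnc_volume()]. The AP origin shifts; the returned
#'   volume carries an `origin_ap` attribute with the offset in μm.
#' @export
crop_vnc <- function(volume, box = NULL, margin = 2L, channel = 1L) {
  stopifnot(inherits(volume, "vnc_volume"))
  d <- dim(volume)[1:3]
  if (is.null(box)) {
    ref <- get_channel(volume, channel)$intensities
    if (max(ref) <= min(ref)) abort("empty foreground: volume has no contrast to crop to")
    thr <- otsu_threshold(ref)
    fg <- which(ref > thr, arr.ind = TRUE)
    if (nrow(fg) == 0L) abort("empty foreground: nothing above threshold")
    box <- t(apply(fg, 2, range))
    box[, 1] <- pmax(box[, 1] - margin, 1L)
    box[, 2] <- pmin(box[, 2] + margin, d)
  } else {
    box <- matrix(as.integer(box), nrow = 3)
    if (any(box[, 1] < 1L) || any(box[, 2] > d) || any(box[, 1] > box[, 2])) {
      abort("`box` must lie inside the volume with lower <= upper per axis")
    }
  }
  idx <- lapply(1:3, function(a) seq.int(box[a, 1], box[a, 2]))
  x <- if (length(dim(volume)) == 4L) {
    volume$intensities[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  } else {
    volume$intensities[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out <- vnc_volume(x, volume$pitch, volume$channels)
  attr(out, "origin_ap") <- (box[1, 1] - 1L) * volume$pitch[["ap"]]
  out
}

#' Take the left or right medio-lateral half of a volume
#'
#' Correlation matrices are conventionally computed per hemisegment; this
#' splits a bilaterally symmetric volume at the ML midline. With an odd ML width the
#' midline column goes to the left half, so left and right reassemble to the
#' original volume.
#'
#' @param volume a [vnc_volume()].
#' @param side `"left"` or `"right"`.
#' @return A [vnc_volume()] covering the requested ML half.
#' @export
split_hemisegment <- function(volume, side = c("left", "right")) {
  stopifnot(inherits(volume, "vnc_volume"))
  side <- match.arg(side)
  w <- dim(volume)[3L]
  if (w < 2L) abort("ML extent must be at least 2 voxels")
  mid <- ceiling(w / 2)
  cols <- if (side == "left") seq_len(mid) else seq.int(mid + 1L, w)
  x <- if (length(dim(volume)) == 4L) {
    volume$intensities[, , cols, , drop = FALSE]
  } else {
    volume$intensities[, , cols, drop = FALSE]
  }
  vnc_volume(x, volume$pitch, volume$channels)
}

#' Ordered transverse sections from AP binning
#'
#' `slab_series` holds the ordered transverse (DV x ML) sections produced by
#' [bin_and_project()]: one per AP bin, each the maximum-intensity projection
#' over that bin's planes.
#'
#' @param sections list of DV x ML numeric matrices.
#' @param bin_length realised bin length in μm (`planes_per_bin * pitch`).
#' @param planes_per_bin integer number of planes per bin.
#' @param pitch in-plane (isotropic) pixel size in μm.
#' @param origin_ap AP position (μm) of the anterior face of the first bin.
#' @return A `slab_series` object.
#' @export
slab_series <- function(sections, bin_length, planes_per_bin, pitch,
                        origin_ap = 0) {
  if (!is.list(sections) || length(sections) < 2L) {
    abort("a slab series needs at least 2 sections")
  }
  stopifnot(isTRUE(all.equal(bin_length, planes_per_bin * pitch)))
  structure(
    list(sections = sections, bin_length = bin_length,
         planes_per_bin = as.integer(planes_per_bin), pitch = pitch,
         origin_ap = origin_ap),
    class = "slab_series"
  )
}

#' @export
length.slab_series <- function(x) length(x$sections)

#' @export
print.slab_series <- function(x, ...) {
  cat("<slab_series> ", length(x), " sections of ",
      paste(dim(x$sections[[1]]), collapse = " x "),
      " px (DV x ML), bin ", signif(x$bin_length, 4), " μm (",
      x$planes_per_bin, " planes)\n", sep = "")
  invisible(x)
}

# AP positions (um) of bin centres
bin_positions <- function(slabs) {
  slabs$origin_ap + (seq_along(slabs$sections) - 0.5) * slabs$bin_length
}

#' Bin the AP axis and maximum-project each bin
#'
#' Splits an isotropic volume into consecutive AP bins of fixed physical
#' length and computes, within each bin, the voxelwise maximum-intensity
#' projection along AP, yielding one transverse section per bin. A trailing
#' partial bin is dropped rather than padded, to avoid a systematically dimmer
#' final section. At the reference calibration (1.65 μm bins on a 0.15 μm
#' isotropic grid) each bin spans eleven planes.
#'
#' @param volume an isotropic [vnc_volume()] (single channel is used).
#' @param bin_length bin length in μm; must be at least one voxel. The realised
#'   bin length is `round(bin_length / pitch)` planes times the pitch.
#' @param channel channel to project.
#' @return A [slab_series()].
#' @export
bin_and_project <- function(volume, bin_length = 1.65, channel = 1L) {
  stopifnot(inherits(volume, "vnc_volume"))
  if (!is_isotropic(volume)) {
    abort("volume must be isotropic; call rescale_isotropic() first")
  }
  pitch <- volume$pitch[["ap"]]
  if (bin_length < pitch) abort("`bin_length` must be >= the voxel pitch")
  ppb <- max(1L, round(bin_length / pitch))
  x <- get_channel(volume, channel)$intensities
  n_bins <- dim(x)[1L] %/% ppb
  if (n_bins < 2L) abort("fewer than 2 complete bins; stack too short for this bin length")
  sections <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    planes <- x[seq.int((b - 1L) * ppb + 1L, b * ppb), , , drop = FALSE]
    sections[[b]] <- apply(planes, c(2, 3), max)
  }
  origin <- attr(volume, "origin_ap")
  slab_series(sections, ppb * pitch, ppb, pitch,
              origin_ap = if (is.null(origin)) 0 else origin)
}

#' Measure the AP length of the nerve cord
#'
#' Thresholds the reference channel and reports the AP extent (μm) of the
#' foreground bounding box — the standard condensation readout.
#'
#' @param volume a [vnc_volume()].
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param channel reference channel.
#' @return Length in μm (a single number).
#' @export
vnc_length <- function(volume, threshold_method = "otsu", channel = 1L) {
  stopifnot(inherits(volume, "vnc_volume"))
  x <- get_channel(volume, channel)$intensities
  if (max(x) <= min(x)) abort("empty foreground: volume has no contrast")
  thr <- resolve_threshold(x, threshold_method)
  fg <- which(apply(x, 1, max) > thr)
  if (length(fg) == 0L) abort("empty foreground: nothing above threshold")
  (max(fg) - min(fg) + 1L) * volume$pitch[["ap"]]
}

#' Persist a slab series as a multi-page TIFF plus JSON sidecar
#' @param slabs a [slab_series()].
#' @param path output TIFF path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_slabs <- function(slabs, path) {
  stopifnot(inherits(slabs, "slab_series"))
  scale <- max(unlist(lapply(slabs$sections, max)), 1e-12)
  tiff::writeTIFF(lapply(slabs$sections, function(s) pmin(s / scale, 1)),
                  path, bits.per.sample = 32L, compression = "deflate")
  jsonlite::write_json(
    list(bin_length = slabs$bin_length, planes_per_bin = slabs$planes_per_bin,
         pitch = slabs$pitch, origin_ap = slabs$origin_ap, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slab series written by [write_slabs()]
#' @param path TIFF path with `<path>.json` sidecar.
#' @return A [slab_series()].
#' @export
read_slabs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sections <- lapply(pages, function(p) p * meta$scale)
  slab_series(sections, meta$bin_length, meta$planes_per_bin, meta$pitch,
              meta$origin_ap)
}
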