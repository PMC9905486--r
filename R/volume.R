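#' Calibrated intensity volume
#'
#' `vnc_volume` is the container every spatial stage of the pipeline consumes:
#' a non-negative 3D intensity grid in canonical axis order
#' (AP, DV, ML) — anterior-posterior, dorso-ventral, medio-lateral — with a
#' voxel pitch in micrometres per axis. A fourth dimension, if present, indexes
#' channels. Physical positions follow the half-voxel convention: the centre of
#' 1-based voxel `i` lies at `(i - 0.5) * pitch`, with AP increasing from
#' anterior to posterior.
#'
#' @param intensities numeric array, 3D `(AP, DV, ML)` or 4D with a trailing
#'   channel dimension; all values must be finite and non-negative.
#' @param pitch numeric length-3 voxel pitch in micrometres, order
#'   `(AP, DV, ML)`; a scalar is recycled (isotropic).
#' @param channels optional character vector of channel labels.
#' @return A `vnc_volume` object.
#' @examples
#' v <- vnc_volume(array(1, c(8, 4, 4)), pitch = 0.5)
#' dim(v)
#' @export
vnc_volume <- function(intensities, pitch, channels = NULL) {
  if (!is.array(intensities) || !length(dim(intensities)) %in% c(3L, 4L)) {
    abort("`intensities` must be a 3D (AP, DV, ML) or 4D (AP, DV, ML, channel) array.")
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    abort("`intensities` must be finite and non-negative.")
  }
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0)) {
    abort("`pitch` must be 3 positive voxel sizes in μm (AP, DV, ML).")
  }
  names(pitch) <- c("ap", "dv", "ml")
  nch <- if (length(dim(intensities)) == 4L) dim(intensities)[4L] else 1L
  if (!is.null(channels) && length(channels) != nch) {
    abort("`channels` must have one label per channel.")
  }
  structure(
    list(intensities = intensities, pitch = pitch, channels = channels),
    class = "vnc_volume"
  )
}

#' @export
dim.vnc_volume <- function(x) dim(x$intensities)

#' @export
print.vnc_volume <- function(x, ...) {
  d <- dim(x)
  ext <- round(d[1:3] * x$pitch, 2)
  cat("<vnc_volume> ", paste(d, collapse = " x "),
      " voxels (AP x DV x ML", if (length(d) == 4L) " x C", ")\n", sep = "")
  cat("  pitch (μm):", paste(signif(x$pitch, 4), collapse = " x "),
      " extent (μm):", paste(ext, collapse = " x "), "\n")
  invisible(x)
}

#' Extract one channel of a volume
#'
#' @param volume a [vnc_volume()].
#' @param channel channel index or label (ignored for single-channel volumes).
#' @return A single-channel `vnc_volume`.
#' @export
get_channel <- function(volume, channel = 1L) {
  stopifnot(inherits(volume, "vnc_volume"))
  if (length(dim(volume)) == 3L) return(volume)
  if (is.character(channel)) {
    channel <- match(channel, volume$channels)
    if (is.na(channel)) abort("unknown channel label")
  }
  vnc_volume(volume$intensities[, , , channel, drop = TRUE], volume$pitch)
}

# AP positions (um) of voxel centres
ap_positions <- function(volume) {
  (seq_len(dim(volume)[1L]) - 0.5) * volume$pitch[["ap"]]
}

# single global Otsu threshold (EBImage's otsu is per-slice on 3D arrays)
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) abort("cannot threshold a constant image")
  EBImage::otsu(matrix(as.numeric(x), ncol = 1L), range = rng, levels = 256L)
}

resolve_threshold <- function(x, threshold_method) {
  if (is.numeric(threshold_method)) return(threshold_method)
  switch(match.arg(threshold_method, c("otsu")), otsu = otsu_threshold(x))
}

#' Read a TIFF stack into a calibrated volume
#'
#' Reads a multi-page (grey or multi-sample) TIFF and canonicalises it to
#' (AP, DV, ML)(, channel) order. Voxel pitch is taken, in order of priority,
#' from the `pitch` argument, a JSON sidecar written by [write_stack()]
#' (`<path>.json`), or OME `PhysicalSizeX/Y/Z` attributes in the ImageDescription
#' tag. If none is available an error asks for explicit pitches.
#'
#' @param path TIFF file path.
#' @param axis_spec three-letter axis order of the file, from the set
#'   `z` (page = AP), `y` (row), `x` (column); `"zyx"` (default) maps pages to
#'   AP, rows to DV and columns to ML.
#' @param pitch optional length-3 (or scalar) voxel pitch in μm (AP, DV, ML),
#'   overriding metadata.
#' @return A [vnc_volume()].
#' @export
read_stack <- function(path, axis_spec = "zyx", pitch = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read '", path, "'"))
  if (!identical(sort(strsplit(axis_spec, "")[[1]]), c("x", "y", "z"))) {
    abort("`axis_spec` must be a permutation of \"zyx\"")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  if (length(d1) == 3L) {
    arr <- array(0, c(length(pages), d1))
    for (k in seq_along(pages)) arr[k, , , ] <- pages[[k]]
  } else {
    arr <- array(0, c(length(pages), d1))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  }
  # file order is (page, row, col); axis_spec names their anatomical meaning.
  # Reorder so AP (z), DV (y), ML (x) come first, second, third.
  perm <- match(c("z", "y", "x"), strsplit(axis_spec, "")[[1]])
  if (length(dim(arr)) == 4L) {
    arr <- aperm(arr, c(perm, 4L))
  } else {
    arr <- aperm(arr, perm)
  }
  meta <- read_stack_metadata(path, pages)
  if (!is.null(meta$scale)) arr <- arr * meta$scale
  if (is.null(pitch)) pitch <- meta$pitch
  if (is.null(pitch)) {
    abort(paste0("no voxel calibration found for '", path,
                 "'; supply `pitch` (μm per axis) explicitly"))
  }
  vnc_volume(arr, pitch)
}

read_stack_metadata <- function(path, pages) {
  out <- list(pitch = NULL, scale = NULL)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pitch_um)) out$pitch <- as.numeric(meta$pitch_um)
    if (!is.null(meta$scale)) out$scale <- as.numeric(meta$scale)
    return(out)
  }
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && grepl("PhysicalSize", desc)) {
    get1 <- function(axis) {
      m <- regmatches(desc, regexec(
        paste0("PhysicalSize", axis, "=\"([0-9.eE+-]+)\""), desc))[[1]]
      if (length(m) == 2L) as.numeric(m[2]) else NA_real_
    }
    p <- c(get1("Z"), get1("Y"), get1("X"))
    if (!anyNA(p)) out$pitch <- p
  }
  out
}

#' Write a volume as a multi-page TIFF with a calibration sidecar
#'
#' Pages are AP sections (rows DV, columns ML); intensities are rescaled to
#' `[0, 1]` by `scale` and stored as 32-bit float. Voxel pitches and the scale
#' go to a JSON sidecar `<path>.json`; [read_stack()] uses it to restore the
#' original intensity scale and calibration, so a write/read round trip is an
#' identity up to float precision.
#'
#' @param volume a [vnc_volume()].
#' @param path output file path.
#' @param scale divisor mapping intensities into `[0, 1]`; default the volume
#'   maximum (or 1 for an all-zero volume).
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, scale = NULL) {
  stopifnot(inherits(volume, "vnc_volume"))
  x <- get_channel(volume)$intensities
  if (is.null(scale)) scale <- max(x, 1e-12)
  pages <- lapply(seq_len(dim(x)[1]), function(i) pmin(x[i, , ] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate")
  jsonlite::write_json(
    list(pitch_um = unname(volume$pitch), axis_order = "zyx", scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
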