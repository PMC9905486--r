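#' Full node-architecture analysis of a calibrated stack
#'
#' Runs the complete spatial-correlation pipeline on one volume: isotropic
#' rescaling (if needed), optional hemisegment split, AP binning with per-bin
#' maximum-intensity projection, the pairwise-registered self-correlation
#' matrix, automated node detection, node-anchored trace extraction, integer-
#' bin alignment in the reference window, trace averaging, and internodal
#' architecture metrics.
#'
#' @param volume a [vnc_volume()].
#' @param bin_length AP bin length in μm.
#' @param opts a [reg_options()].
#' @param hemiside `"both"` (full ML width), `"left"` or `"right"`.
#' @param min_prominence,min_separation node-peak filters, see
#'   [detect_nodes()]; `min_separation` (half the expected segmental period)
#'   also bounds the trace-alignment shift search, which removes the
#'   whole-period degeneracy of aligning periodic profiles.
#' @param window AP alignment window in μm, see [align_traces()].
#' @return A `vnc_architecture` list: `slabs`, `matrix`, `nodes` (bin
#'   indices), `traces`, `mean_trace`, `metrics`.
#' @export
node_architecture <- function(volume, bin_length = 1.65, opts = reg_options(),
                              hemiside = c("both", "left", "right"),
                              min_prominence = 0.05, min_separation = 14,
                              window = c(25, 57)) {
  stopifnot(inherits(volume, "vnc_volume"))
  hemiside <- match.arg(hemiside)
  if (!is_isotropic(volume)) volume <- rescale_isotropic(volume)
  if (hemiside != "both") volume <- split_hemisegment(volume, hemiside)
  slabs <- bin_and_project(volume, bin_length)
  cm <- self_correlation_matrix(slabs, opts)
  nodes <- detect_nodes(cm, min_prominence, min_separation)
  if (length(nodes) == 0L) {
    abort("no nodes detected; lower `min_prominence` or check the stack")
  }
  traces <- lapply(nodes, function(b) extract_trace(cm, b))
  aligned <- align_traces(traces, window = window, max_shift = min_separation)
  mean_trace <- average_traces(aligned)
  # metrics are read off the well-covered core of the average; sparse tails
  # contributed by shifted traces would fake extra peaks
  core <- which(mean_trace$n >= ceiling(max(mean_trace$n) / 2))
  mean_core <- node_trace(mean_trace$position[min(core):max(core)],
                          mean_trace$value[min(core):max(core)],
                          sd = mean_trace$sd[min(core):max(core)],
                          n = mean_trace$n[min(core):max(core)],
                          bin_length = trace_bin_length(mean_trace))
  metrics <- internodal_metrics(mean_core, min_prominence, min_separation)
  structure(
    list(slabs = slabs, matrix = cm, nodes = nodes, traces = aligned,
         mean_trace = mean_trace, metrics = metrics),
    class = "vnc_architecture"
  )
}

#' @export
print.vnc_architecture <- function(x, ...) {
  cat("<vnc_architecture> ", length(x$nodes), " nodes over ",
      nrow(x$matrix), " AP bins\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @rdname node_architecture
#' @param x a `vnc_architecture` object.
#' @param ... unused.
#' @return `glance()`: one-row tibble with node count, mean internodal
#'   distance and mean node-to-minimum offset.
#' @method glance vnc_architecture
#' @export
glance.vnc_architecture <- function(x, ...) {
  glance(x$metrics)
}
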