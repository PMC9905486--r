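#' Node-anchored correlation trace
#'
#' A 1D profile of correlation scores along the AP axis, as extracted from a
#' correlation matrix around a node row ([extract_trace()]) or averaged across
#' nodes/embryos ([average_traces()]). Stored as a tibble so traces pipe
#' straight into dplyr/ggplot2.
#'
#' @param position AP positions in μm (strictly increasing, one bin apart).
#' @param value correlation scores in `[0, 1]` (`NA` allowed).
#' @param sd optional per-position spread.
#' @param n number of contributing traces per position.
#' @param bin_length grid step in μm.
#' @param reference_bin matrix row the trace is anchored on (`NA` for
#'   averaged or analytic traces).
#' @param edge logical; `TRUE` when the anchor row sat on the matrix edge and
#'   only two rows contributed.
#' @return A `node_trace` tibble with columns `position`, `value`, `sd`, `n`.
#' @export
node_trace <- function(position, value, sd = NA_real_, n = 1L,
                       bin_length, reference_bin = NA_integer_, edge = FALSE) {
  stopifnot(length(position) == length(value))
  if (length(position) > 1L) {
    steps <- diff(position)
    if (any(steps <= 0) || diff(range(steps)) > 1e-6 * bin_length) {
      abort("`position` must increase in uniform steps of one bin")
    }
  }
  out <- tibble::tibble(position = as.numeric(position),
                        value = as.numeric(value),
                        sd = rep_len(as.numeric(sd), length(position)),
                        n = rep_len(as.integer(n), length(position)))
  class(out) <- c("node_trace", class(out))
  attr(out, "bin_length") <- bin_length
  attr(out, "reference_bin") <- reference_bin
  attr(out, "edge") <- isTRUE(edge)
  out
}

trace_bin_length <- function(trace) attr(trace, "bin_length")

# --- peak finding -----------------------------------------------------------

# local maxima of a profile with topographic prominence and minimum-separation
# filtering (greedy, highest peak first); returns sorted indices
find_peaks <- function(x, min_prominence = 0, min_separation_bins = 1) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  x[is.na(x)] <- -Inf
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[is.finite(x[cand])]
  if (length(cand) == 0L) return(integer(0))
  # topographic prominence: height above the higher of the two key saddles
  # (the lowest points crossed before reaching taller ground on either side);
  # the global maximum has open prominence
  prominence <- vapply(cand, function(i) {
    saddle <- -Inf
    for (dir in c(-1L, 1L)) {
      j <- i
      lowest <- x[i]
      repeat {
        j <- j + dir
        if (j < 1L || j > n) break
        if (x[j] > x[i]) { saddle <- max(saddle, lowest); break }
        lowest <- min(lowest, x[j])
      }
    }
    if (is.finite(saddle)) x[i] - saddle else Inf  # global max: open prominence
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) == 0L) return(integer(0))
  keep <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in keep) {
    if (all(abs(i - chosen) >= min_separation_bins)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

# sub-bin refinement of an extremum by a 3-point parabola
refine_parabolic <- function(x, i) {
  if (i <= 1L || i >= length(x) || anyNA(x[(i - 1):(i + 1)])) return(i)
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (abs(denom) < 1e-12) return(i)
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  i + max(min(delta, 0.5), -0.5)
}

# fractional index of an internodal minimum as the intersection of lines
# fitted to the descent (peak -> min) and recovery (min -> next peak) limbs;
# falls back to 3-point parabolic refinement when either fit is degenerate
refine_min_intersection <- function(x, left_peak, i_min, right_peak) {
  fit <- function(idx) {
    idx <- idx[!is.na(x[idx])]
    if (length(idx) < 3L) return(NULL)
    b <- stats::cov(idx, x[idx]) / stats::var(idx)
    c(intercept = mean(x[idx]) - b * mean(idx), slope = b)
  }
  dn <- fit(seq.int(left_peak + 1L, i_min))
  up <- fit(seq.int(i_min, right_peak - 1L))
  if (is.null(dn) || is.null(up) || dn["slope"] >= 0 || up["slope"] <= 0) {
    return(refine_parabolic(x, i_min))
  }
  i_star <- (up["intercept"] - dn["intercept"]) / (dn["slope"] - up["slope"])
  # keep the refinement inside the internode; otherwise distrust the fits
  if (i_star <= left_peak || i_star >= right_peak) {
    return(refine_parabolic(x, i_min))
  }
  unname(i_star)
}

# sub-bin position of an extremum as the centroid of its plateau: correlation
# peaks around nodes are flat-topped (dispersion stays below the tube width
# near the node window), so the centroid of the region within `tol` of the
# extremum is far more stable than the raw argmax. Sharp extrema reduce to
# the usual 3-point refinement. `sign` = +1 for maxima, -1 for minima.
refine_extremum <- function(x, i, sign = 1, tol = 0.05) {
  v <- sign * x
  l <- i
  while (l > 1L && !is.na(v[l - 1L]) && v[l - 1L] >= v[i] - tol) l <- l - 1L
  r <- i
  n <- length(v)
  while (r < n && !is.na(v[r + 1L]) && v[r + 1L] >= v[i] - tol) r <- r + 1L
  if (r - l < 2L) return(refine_parabolic(x, i))
  idx <- l:r
  w <- v[idx] - (v[i] - tol)
  sum(idx * w) / sum(w)
}

#' Detect segmental 3D nodes in a self-correlation matrix
#'
#' In the manual workflow the high-correlation regions are identified by
#' eye; here detection is automated: the mean off-diagonal correlation of each row
#' is treated as a 1D profile whose local maxima — filtered by topographic
#' prominence and a minimum AP separation — are the nodes, one per segment in
#' a well-formed cord.
#'
#' @param matrix a self `corr_matrix`.
#' @param min_prominence minimum topographic prominence of a peak
#'   (correlation units).
#' @param min_separation minimum AP distance between nodes, μm; the
#'   conventional choice is half the expected segmental period.
#' @return Integer vector of node bin indices (possibly empty), sorted by AP.
#' @export
detect_nodes <- function(matrix, min_prominence = 0.05, min_separation = 14) {
  stopifnot(inherits(matrix, "corr_matrix"))
  if (nrow(matrix) != ncol(matrix)) abort("node detection needs a self-matrix")
  vals <- unclass(matrix)
  profile <- vapply(seq_len(nrow(vals)), function(i) {
    mean(vals[i, -i], na.rm = TRUE)
  }, numeric(1))
  sep_bins <- max(1, min_separation / attr(matrix, "bin_length"))
  find_peaks(profile, min_prominence, sep_bins)
}

#' Extract the correlation trace anchored at a node
#'
#' The trace value at AP bin j is the mean correlation of the three matrix
#' rows centred on the node (node - 1, node, node + 1) at column j, with
#' diagonal entries and missing values excluded. At a matrix edge the two
#' available rows are used and the trace is flagged.
#'
#' @param matrix a self `corr_matrix`.
#' @param node_bin anchor row (1-based bin index).
#' @return A [node_trace()] on the matrix's AP grid.
#' @export
extract_trace <- function(matrix, node_bin) {
  stopifnot(inherits(matrix, "corr_matrix"))
  n <- nrow(matrix)
  if (node_bin < 1L || node_bin > n) abort("`node_bin` outside the matrix")
  rows <- intersect((node_bin - 1L):(node_bin + 1L), seq_len(n))
  vals <- unclass(matrix)[rows, , drop = FALSE]
  for (k in seq_along(rows)) vals[k, rows[k]] <- NA  # drop diagonal entries
  value <- colMeans(vals, na.rm = TRUE)
  value[!is.finite(value)] <- NA_real_
  bl <- attr(matrix, "bin_length")
  node_trace(position = attr(matrix, "origin_ap") + (seq_len(n) - 0.5) * bl,
             value = value, bin_length = bl, reference_bin = node_bin,
             edge = length(rows) < 3L)
}

# integer grid index of each trace position on the shared bin lattice
trace_grid <- function(trace) {
  round(trace$position / trace_bin_length(trace) - 0.5)
}

shift_trace <- function(trace, shift_bins) {
  out <- trace
  out$position <- trace$position + shift_bins * trace_bin_length(trace)
  attr(out, "shift_bins") <- shift_bins
  out
}

#' Align traces by integer-bin AP offsets
#'
#' Shifts each trace by a whole number of bins to maximise the overlap of its
#' peaks with a running reference inside the given AP window (default
#' 25-57 μm), the first trace serving as the initial reference. Shifting by
#' whole bins keeps scores on the measurement grid; sub-bin shifts would
#' interpolate correlation values.
#'
#' @param traces list of [node_trace()]s sharing one bin length.
#' @param window AP interval (μm, on the reference grid) in which overlap is
#'   maximised.
#' @param max_shift largest allowed shift magnitude in μm.
#' @return The list of shifted traces; each carries its shift (bins) in the
#'   `shift_bins` attribute.
#' @export
align_traces <- function(traces, window = c(25, 57), max_shift = Inf) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  bl <- trace_bin_length(traces[[1]])
  for (t in traces) {
    if (!isTRUE(all.equal(trace_bin_length(t), bl))) {
      abort("all traces must share one bin length")
    }
  }
  if (length(traces) == 1L) {
    return(list(shift_trace(traces[[1]], 0L)))
  }
  ref <- traces[[1]]
  ref_grid <- trace_grid(ref)
  in_window <- ref$position >= window[1] & ref$position <= window[2]
  if (!any(in_window)) abort("alignment window lies outside the reference trace")
  ref_sum <- ref$value
  ref_n <- as.numeric(!is.na(ref$value))
  ref_sum[is.na(ref_sum)] <- 0
  out <- list(shift_trace(traces[[1]], 0L))
  s_max <- if (is.finite(max_shift)) floor(max_shift / bl) else length(ref_grid)
  for (k in seq_along(traces)[-1]) {
    tr <- traces[[k]]
    g <- trace_grid(tr)
    ref_mean <- ifelse(ref_n > 0, ref_sum / pmax(ref_n, 1), NA)
    best <- c(score = -Inf, shift = 0)
    # a candidate shift must keep at least half the window covered; tiny
    # overlaps produce spuriously perfect correlations
    min_cover <- max(3L, floor(sum(in_window) / 2))
    for (s in seq.int(-s_max, s_max)) {
      idx <- match(g + s, ref_grid)
      ok <- !is.na(idx) & in_window[ifelse(is.na(idx), 1L, idx)] &
        !is.na(tr$value) & !is.na(ref_mean[ifelse(is.na(idx), 1L, idx)])
      if (sum(ok) < min_cover) next
      a <- tr$value[ok]
      b <- ref_mean[idx[ok]]
      sc <- if (sd(a) > 0 && sd(b) > 0) stats::cor(a, b) else -mean((a - b)^2)
      if (sc > best["score"] + 1e-12 ||
          (abs(sc - best["score"]) <= 1e-12 && abs(s) < abs(best["shift"]))) {
        best <- c(score = sc, shift = s)
      }
    }
    shifted <- shift_trace(tr, as.integer(best["shift"]))
    out[[k]] <- shifted
    idx <- match(trace_grid(shifted), ref_grid)
    ok <- !is.na(idx) & !is.na(shifted$value)
    ref_sum[idx[ok]] <- ref_sum[idx[ok]] + shifted$value[ok]
    ref_n[idx[ok]] <- ref_n[idx[ok]] + 1
  }
  out
}

#' Average aligned traces
#'
#' Per-position mean and sample (n - 1) standard deviation over the traces
#' contributing at that position; positions covered by a single trace get an
#' undefined (`NA`) sd.
#'
#' @param aligned list of [node_trace()]s on a common grid (see
#'   [align_traces()]).
#' @return A [node_trace()] with `sd` and `n` filled in.
#' @export
average_traces <- function(aligned) {
  stopifnot(is.list(aligned), length(aligned) >= 1L)
  bl <- trace_bin_length(aligned[[1]])
  grids <- lapply(aligned, trace_grid)
  rng <- range(unlist(grids))
  grid <- seq.int(rng[1], rng[2])
  acc <- matrix(NA_real_, length(aligned), length(grid))
  for (k in seq_along(aligned)) {
    acc[k, match(grids[[k]], grid)] <- aligned[[k]]$value
  }
  n <- colSums(!is.na(acc))
  keep <- n > 0
  mean_v <- colMeans(acc, na.rm = TRUE)
  sd_v <- apply(acc, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2L) sd(col) else NA_real_
  })
  node_trace(position = (grid[keep] + 0.5) * bl, value = mean_v[keep],
             sd = sd_v[keep], n = n[keep], bin_length = bl)
}

#' Internodal architecture metrics from a correlation trace
#'
#' Nodes are the trace's prominent maxima; their successive AP differences are
#' the internodal distances. Within each internode the trace minimum is
#' located and its (positive = posterior) offset from the preceding node
#' reported. Peak and trough positions are refined to sub-bin precision by
#' 3-point parabolic interpolation; detection itself stays on the bin grid.
#'
#' @param trace a [node_trace()] spanning at least two node peaks.
#' @param min_prominence,min_separation peak filters as in [detect_nodes()].
#' @return A `node_metrics` list: `node_positions`, `internodal_distances`,
#'   `mean_internodal_distance`, `node_to_min_offsets`, `n_nodes` (positions
#'   and distances in μm).
#' @export
internodal_metrics <- function(trace, min_prominence = 0.05,
                               min_separation = 14) {
  stopifnot(inherits(trace, "node_trace"))
  bl <- trace_bin_length(trace)
  x <- trace$value
  peaks <- find_peaks(x, min_prominence, max(1, min_separation / bl))
  if (length(peaks) < 2L) abort("insufficient nodes: fewer than 2 trace peaks")
  pos_of <- function(i_frac) {
    trace$position[1] + (i_frac - 1) * bl
  }
  node_pos <- vapply(peaks, function(i) pos_of(refine_extremum(x, i, 1, tol = 0.02)),
                     numeric(1))
  offsets <- vapply(seq_len(length(peaks) - 1L), function(k) {
    span <- seq.int(peaks[k] + 1L, peaks[k + 1L] - 1L)
    if (length(span) == 0L) return(NA_real_)
    vals <- x[span]
    if (all(is.na(vals))) return(NA_real_)
    i_min <- span[which.min(vals)]
    # the internodal minimum sits at the kink between the descent and
    # recovery limbs; intersecting least-squares lines fitted to the two
    # limbs averages the per-bin noise out and avoids the bias of a raw
    # argmin on a profile whose recovery is much shallower than its descent
    pos_of(refine_min_intersection(x, peaks[k], i_min, peaks[k + 1L])) -
      node_pos[k]
  }, numeric(1))
  structure(
    list(node_positions = node_pos,
         internodal_distances = diff(node_pos),
         mean_internodal_distance = mean(diff(node_pos)),
         node_to_min_offsets = offsets,
         n_nodes = length(peaks)),
    class = "node_metrics"
  )
}

#' @export
print.node_metrics <- function(x, ...) {
  cat("<node_metrics> ", x$n_nodes, " nodes; mean internodal distance ",
      sprintf("%.2f", x$mean_internodal_distance), " μm; mean node-to-minimum offset ",
      sprintf("%.2f", mean(x$node_to_min_offsets, na.rm = TRUE)), " μm\n",
      sep = "")
  invisible(x)
}

#' @rdname internodal_metrics
#' @param x a `node_metrics` object.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per internode (`node_position`,
#'   `internodal_distance`, `node_to_min_offset`); `glance()`: a one-row
#'   summary tibble.
#' @method tidy node_metrics
#' @export
tidy.node_metrics <- function(x, ...) {
  k <- seq_len(x$n_nodes - 1L)
  tibble::tibble(internode = k,
                 node_position = x$node_positions[k],
                 internodal_distance = x$internodal_distances,
                 node_to_min_offset = x$node_to_min_offsets)
}

#' @rdname internodal_metrics
#' @method glance node_metrics
#' @export
glance.node_metrics <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes,
                 mean_internodal_distance = x$mean_internodal_distance,
                 sd_internodal_distance = sd(x$internodal_distances),
                 mean_node_to_min_offset = mean(x$node_to_min_offsets, na.rm = TRUE))
}

#' Write traces to CSV
#' @param trace a [node_trace()].
#' @param path output CSV path (`position_um`, `mean`, `sd`, `n`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(position_um = trace$position, mean = trace$value,
               sd = trace$sd, n = trace$n),
    path, row.names = FALSE)
  invisible(path)
}
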