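#' Heatmap of a correlation matrix
#'
#' The conventional 0-1 colour-coded representation: AP bin against AP bin,
#' segmental structure appearing as periodic bands.
#'
#' @param object a `corr_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot corr_matrix
#' @export
autoplot.corr_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$position_a, .data$position_b,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80",
                                  name = "correlation") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "AP position (μm)", y = "AP position (μm)") +
    ggplot2::theme_minimal()
}

#' Correlation trace with node bars
#'
#' Mean correlation profile along AP with a ± SD ribbon and vertical
#' bars at the detected node maxima.
#'
#' @param object a [node_trace()].
#' @param min_prominence,min_separation peak filters for the node bars; set
#'   `min_prominence = NA` to suppress the bars.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot node_trace
#' @export
autoplot.node_trace <- function(object, min_prominence = 0.05,
                                min_separation = 14, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$value))
  if (any(is.finite(df$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      fill = "red", alpha = 0.15)
  }
  if (!is.na(min_prominence)) {
    peaks <- find_peaks(df$value, min_prominence,
                        max(1, min_separation / trace_bin_length(object)))
    if (length(peaks)) {
      p <- p + ggplot2::geom_vline(xintercept = df$position[peaks],
                                   colour = "darkgreen", linewidth = 1,
                                   alpha = 0.5)
    }
  }
  p +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "AP position (μm)", y = "correlation score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Distribution of the resampled asymmetry statistic
#'
#' @param object a `gradient_stats` from [resample_r()].
#' @param ... unused.
#' @return A ggplot histogram of the replicate r values with zero marked.
#' @method autoplot gradient_stats
#' @export
autoplot.gradient_stats <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$r, colour = "red") +
    ggplot2::labs(x = "r (internodal asymmetry)", y = "replicates") +
    ggplot2::theme_minimal()
}
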