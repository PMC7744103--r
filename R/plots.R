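# ggplot2 displays for the main result types.

#' @method autoplot stellate_raster
#' @export
autoplot.stellate_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = "trial") +
    ggplot2::theme_classic()
}

#' @method autoplot stellate_psth
#' @export
autoplot.stellate_psth <- function(object, ...) {
  bin <- attr(object, "bin") %||% 1
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start_ms + bin / 2,
                                       y = .data$count)) +
    ggplot2::geom_col(width = bin, fill = "grey30") +
    ggplot2::labs(x = "time (ms)", y = "spike count") +
    ggplot2::theme_classic()
}

#' @method autoplot stellate_wcss
#' @export
autoplot.stellate_wcss <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters K",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_classic()
}

#' @method autoplot stellate_sholl
#' @export
autoplot.stellate_sholl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius_um,
                                       y = .data$crossings)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius from soma (µm)", y = "intersections") +
    ggplot2::theme_classic()
}

#' Plot a clustered feature pair
#'
#' @param clusters A `stellate_kmeans` object.
#' @param profiles The feature table that was clustered.
#' @param x,y Feature columns to display.
#' @return A ggplot.
#' @export
plot_clusters <- function(clusters, profiles, x = "ap_halfwidth_ms",
                          y = "rin_mohm") {
  df <- profiles[profiles$cell_id %in% names(clusters$assignments), ]
  df$cluster <- factor(clusters$assignments[df$cell_id])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::theme_classic()
}

#' Plot a voltage or current trace
#'
#' @param trace Tibble with `time_ms` and `voltage_mv` or `current_pa`.
#' @return A ggplot.
#' @export
plot_trace <- function(trace) {
  ycol <- intersect(c("voltage_mv", "current_pa"), names(trace))[1]
  ylab <- if (ycol == "voltage_mv") "membrane potential (mV)" else "current (pA)"
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_ms, y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = ylab) +
    ggplot2::theme_classic()
}
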