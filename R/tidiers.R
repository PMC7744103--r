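# broom-style tidiers for fitted objects.

#' Tidy a K-means partition
#'
#' One row per cluster with sizes and centroids in original feature units
#' (falling back to the clustering space when no transform was recorded).
#'
#' @param x A `stellate_kmeans` object.
#' @param ... Unused.
#' @return A tibble with `cluster`, `size` and one column per feature.
#' @method tidy stellate_kmeans
#' @export
tidy.stellate_kmeans <- function(x, ...) {
  cen <- x$centers_original %||% x$centers
  out <- as_tibble(cen)
  out$cluster <- seq_len(x$k)
  out$size <- x$sizes
  out[, c("cluster", "size", setdiff(names(out), c("cluster", "size")))]
}

#' @rdname tidy.stellate_kmeans
#' @method glance stellate_kmeans
#' @export
glance.stellate_kmeans <- function(x, ...) {
  tibble(k = x$k, n = length(x$assignments), wcss = x$wcss,
         restarts = x$restarts)
}

#' Tidy chopper metrics
#'
#' @param x A `stellate_chopper` object.
#' @param ... Unused.
#' @return The CV profile tibble.
#' @method tidy stellate_chopper
#' @export
tidy.stellate_chopper <- function(x, ...) {
  x$cv_profile
}

#' @rdname tidy.stellate_chopper
#' @method glance stellate_chopper
#' @export
glance.stellate_chopper <- function(x, ...) {
  tibble(first_spike_sd = x$first_spike_sd,
         adaptation_ratio = x$adaptation_ratio,
         is_sustained_chopper = x$is_sustained_chopper)
}

#' Tidy soma-volume statistics
#'
#' @param x A `stellate_volumes` object.
#' @param ... Unused.
#' @return Per-group summary tibble.
#' @method tidy stellate_volumes
#' @export
tidy.stellate_volumes <- function(x, ...) {
  x$by_group
}

#' @rdname tidy.stellate_volumes
#' @method glance stellate_volumes
#' @export
glance.stellate_volumes <- function(x, ...) {
  tibble(skewness = x$skewness,
         gauss_mu = x$gaussian_fit[["mu"]],
         gauss_sigma = x$gaussian_fit[["sigma"]],
         lognormal_meanlog = x$lognormal_fit[["meanlog"]],
         lognormal_sdlog = x$lognormal_fit[["sdlog"]])
}
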