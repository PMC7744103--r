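# Population-level statistics: soma-volume distributions and two-group
# comparisons.

#' Soma-volume distribution statistics
#'
#' Per-group mean +/- SEM, adjusted Fisher-Pearson sample skewness (the
#' soma-volume distribution of the glycinergic population is positively
#' skewed: many small cells, few large ones), and a Gaussian curve fitted by
#' least squares to the histogram — plus a log-normal fit as a diagnostic
#' for the skew.
#'
#' @param volumes Data frame with `volume_um3` and optionally `group`.
#' @param bin_width Histogram bin width (um^3); defaults to the
#'   Freedman-Diaconis width.
#' @return List of class `stellate_volumes`: `by_group` (tibble `group`,
#'   `n`, `mean`, `sem`), `skewness`, `gaussian_fit` (`mu`, `sigma`,
#'   `amplitude`), `lognormal_fit` (`meanlog`, `sdlog`), `histogram`.
#' @export
volume_stats <- function(volumes, bin_width = NULL) {
  if (!"volume_um3" %in% names(volumes)) {
    abort("`volumes` needs a `volume_um3` column")
  }
  v <- volumes$volume_um3
  if (any(v <= 0)) abort("volumes must be positive")
  grp <- if ("group" %in% names(volumes)) volumes$group else "all"
  by_group <- tibble(volume = v, group = grp) |>
    group_by(.data$group) |>
    summarise(n = n(), mean = mean(.data$volume),
              sem = sd(.data$volume) / sqrt(n()), .groups = "drop")

  skew <- NA_real_
  if (length(v) >= 3) {
    skew <- e1071::skewness(v, type = 2)
  } else {
    warn("fewer than 3 volumes; skewness undefined")
  }

  if (is.null(bin_width)) {
    bin_width <- 2 * stats::IQR(v) / length(v)^(1 / 3)
    if (bin_width <= 0) bin_width <- diff(range(v)) / 10
  }
  breaks <- seq(floor(min(v) / bin_width) * bin_width,
                max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  hd <- tibble(mid = h$mids, count = h$counts)
  gfit <- if (sum(hd$count > 0) < 4) {
    c(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_)
  } else tryCatch({
    fit <- minpack.lm::nlsLM(
      count ~ a * exp(-(mid - mu)^2 / (2 * sigma^2)), data = hd,
      start = list(a = max(hd$count), mu = mean(v), sigma = sd(v)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- coef(fit)
    c(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])),
      amplitude = unname(cf["a"]))
  }, error = function(e) {
    warn("Gaussian histogram fit did not converge")
    c(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_)
  })
  lnfit <- c(meanlog = mean(log(v)), sdlog = sd(log(v)))

  structure(
    list(by_group = by_group, skewness = skew, gaussian_fit = gfit,
         lognormal_fit = lnfit, histogram = hd, bin_width = bin_width),
    class = "stellate_volumes"
  )
}

#' @export
print.stellate_volumes <- function(x, ...) {
  cat(sprintf("soma volumes: skewness %.3g, Gaussian fit mu = %.4g, sigma = %.4g\n",
              x$skewness, x$gaussian_fit[["mu"]], x$gaussian_fit[["sigma"]]))
  print(x$by_group)
  invisible(x)
}

#' Two-group comparison by t test
#'
#' Paired or Welch unpaired t test with per-group mean +/- SEM, the
#' comparison used throughout for group differences.
#'
#' @param a,b Numeric samples.
#' @param paired Paired test (requires equal lengths).
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b)) {
    abort("paired comparison requires equal group sizes")
  }
  tt <- t.test(a, b, paired = paired)
  tibble(
    test = if (paired) "paired t-test" else "Welch t-test",
    statistic = unname(tt$statistic), p_value = tt$p.value,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)),
    mean_b = mean(b), sem_b = sd(b) / sqrt(length(b))
  )
}
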