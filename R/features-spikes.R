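# Action-potential waveform feature extraction.
#
# Threshold follows the 5%-of-peak-dV/dt rule: after subtracting the
# baseline dV/dt produced by the cell's electrotonic charging (estimated by
# a mono-exponential fit to the pre-spike segment), the threshold is the
# voltage at the last upward crossing of 5% of the peak of the spike's first
# derivative before the spike peak.

#' Detect spike peaks in a voltage trace
#'
#' Peaks are local voltage maxima whose preceding dV/dt (within
#' `lookback_ms`) exceeds `dvdt_threshold`; successive peaks are separated by
#' at least `refractory` ms (the earlier peak wins).
#'
#' @param trace Tibble with `time_ms` and `voltage_mv` on a uniform grid.
#' @param dvdt_threshold Minimum preceding dV/dt (V/s). The source analysis
#'   specifies no value; 20 V/s is conventional.
#' @param refractory Minimum peak separation (ms).
#' @param lookback_ms Window before each candidate peak searched for the
#'   dV/dt surge.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
detect_spikes <- function(trace, dvdt_threshold = 20, refractory = 1,
                          lookback_ms = 1) {
  v <- trace$voltage_mv
  n <- length(v)
  if (n < 3L) return(integer())
  dt <- grid_dt(trace$time_ms)
  d <- central_diff(v, dt)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  w <- max(1L, round(lookback_ms / dt))
  cand <- cand[vapply(cand, function(i) {
    max(d[max(1L, i - w):i]) > dvdt_threshold
  }, logical(1))]
  if (length(cand) <= 1L) return(cand)
  keep <- cand[1]
  for (i in cand[-1]) {
    if (trace$time_ms[i] - trace$time_ms[keep[length(keep)]] >= refractory) {
      keep <- c(keep, i)
    }
  }
  keep
}

#' Estimate the baseline dV/dt from electrotonic charging
#'
#' Fits a mono-exponential charging curve `V(t) = V0 + A (1 - exp(-(t -
#' onset)/tau))` to the segment between the step onset and 1 ms before the
#' first spike's dV/dt surge (or the step offset when there is no spike) and
#' returns the fit's analytic derivative sampled on the trace grid, zero
#' before onset. When the fit window holds less than 2 ms of data, or the
#' fit fails, a zero series is returned with attribute `flagged = TRUE` and
#' a warning.
#'
#' @inheritParams detect_spikes
#' @param step_onset Step onset (ms).
#' @param first_spike_peak Time of the first spike peak (ms), or `NULL` for
#'   a spike-free sweep.
#' @param step_offset Step offset (ms), used as the window end when no dV/dt
#'   surge is found.
#' @return Numeric derivative series (mV/ms) on the trace grid, with
#'   attributes `fit` (named vector `v0`, `amp`, `tau`) and `flagged`.
#' @export
estimate_baseline_dvdt <- function(trace, step_onset,
                                   first_spike_peak = NULL,
                                   step_offset = NULL,
                                   dvdt_threshold = 20) {
  t <- trace$time_ms
  v <- trace$voltage_mv
  dt <- grid_dt(t)
  d <- central_diff(v, dt)
  zero <- function(msg) {
    warn(msg)
    structure(numeric(length(t)), flagged = TRUE, fit = NULL)
  }
  t_end <- step_offset %||% max(t)
  if (!is.null(first_spike_peak)) t_end <- min(t_end, first_spike_peak)
  surge <- which(d > dvdt_threshold & t > step_onset & t <= t_end)
  if (length(surge) > 0) t_end <- min(t_end, t[surge[1]] - 1)
  win <- which(t >= step_onset & t <= t_end)
  if (length(win) < 2L || (t_end - step_onset) < 2) {
    return(zero("baseline fit window shorter than 2 ms; using zero baseline"))
  }
  df <- data.frame(tt = t[win] - step_onset, vv = v[win])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vv ~ v0 + amp * (1 - exp(-tt / tau)), data = df,
      start = list(v0 = df$vv[1], amp = df$vv[nrow(df)] - df$vv[1],
                   tau = max(diff(range(df$tt)) / 5, 1)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(zero("baseline charging fit did not converge; using zero baseline"))
  }
  cf <- coef(fit)
  out <- numeric(length(t))
  i <- t >= step_onset
  out[i] <- cf[["amp"]] / cf[["tau"]] * exp(-(t[i] - step_onset) / cf[["tau"]])
  structure(out, fit = c(v0 = cf[["v0"]], amp = cf[["amp"]],
                         tau = cf[["tau"]]), flagged = FALSE)
}

#' Spike threshold by the 5%-of-peak-dV/dt rule
#'
#' Subtracts `baseline` from the trace derivative, takes the derivative peak
#' `d_max` over a window ending at the spike peak, and walks backward from
#' the peak to the last upward crossing of `0.05 * d_max`. Threshold time
#' and voltage are linearly interpolated between the straddling samples.
#'
#' @inheritParams detect_spikes
#' @param peak_idx Spike peak sample index (from [detect_spikes()]).
#' @param baseline Baseline derivative series on the trace grid (mV/ms), or
#'   `NULL` for zero.
#' @param search_ms Length of the pre-peak search window.
#' @return List with `threshold_v` (mV), `threshold_t` (ms), `threshold_idx`
#'   (left straddling sample), `d_max` (mV/ms) and the baseline-subtracted
#'   derivative series `dvdt`.
#' @export
spike_threshold <- function(trace, peak_idx, baseline = NULL, search_ms = 10) {
  t <- trace$time_ms
  v <- trace$voltage_mv
  dt <- grid_dt(t)
  d <- central_diff(v, dt)
  if (!is.null(baseline)) d <- d - as.numeric(baseline)
  from <- max(1L, peak_idx - round(search_ms / dt))
  d_max <- max(d[from:peak_idx])
  if (d_max <= 0) abort("degenerate spike: non-positive peak dV/dt")
  d5 <- 0.05 * d_max
  i <- last_upward_crossing(d, d5, from, peak_idx)
  if (is.na(i)) abort("degenerate spike: no upward 5% dV/dt crossing")
  thr_t <- crossing_time(t, d, i, d5)
  thr_v <- interp_at(t, v, thr_t)
  list(threshold_v = thr_v, threshold_t = thr_t, threshold_idx = i,
       d_max = d_max, dvdt = d)
}

#' Waveform features of one action potential
#'
#' Computes, per the source definitions: height (threshold to peak),
#' halfwidth (interpolated width at threshold + height/2), overshoot (peak
#' re 0 mV), undershoot (most negative excursion re threshold within the
#' post-peak window), AHP latency (peak to undershoot trough) and the AHP
#' metric (voltage 1 ms after the trough minus the trough voltage; positive
#' when the cell is repolarizing back toward rest). The AHP metric is `NA`
#' (flagged) when the next spike's threshold crossing falls within 1 ms of
#' the trough.
#'
#' @inheritParams spike_threshold
#' @param threshold Result of [spike_threshold()] for this peak.
#' @param window_ms Undershoot search window after the peak (ms); truncated
#'   at `next_threshold_t` and at `t_max` when given.
#' @param next_threshold_t Threshold-crossing time of the following spike
#'   (ms), if any.
#' @param t_max Hard window end (ms), e.g. the step offset.
#' @return One-row tibble of spike features (`max_dvdt_vps` is the peak
#'   baseline-subtracted derivative in V/s).
#' @export
ap_features <- function(trace, peak_idx, threshold, window_ms = 10,
                        next_threshold_t = NULL, t_max = NULL) {
  t <- trace$time_ms
  v <- trace$voltage_mv
  thr <- threshold$threshold_v
  peak_v <- v[peak_idx]
  peak_t <- t[peak_idx]
  height <- peak_v - thr
  if (height <= 0) abort("degenerate spike: peak below threshold")

  # Halfwidth between the interpolated crossings of threshold + height/2.
  v_half <- thr + height / 2
  up_i <- last_upward_crossing(v, v_half, threshold$threshold_idx, peak_idx)
  hw <- NA_real_
  if (!is.na(up_i)) {
    t_up <- crossing_time(t, v, up_i, v_half)
    down <- which(v[peak_idx:(length(v) - 1L)] >= v_half &
                    v[(peak_idx + 1L):length(v)] < v_half)
    if (length(down) > 0) {
      j <- peak_idx + down[1] - 1L
      t_down <- crossing_time(t, v, j, v_half)
      hw <- t_down - t_up
    }
  }

  w_end <- peak_t + window_ms
  if (!is.null(next_threshold_t)) w_end <- min(w_end, next_threshold_t)
  if (!is.null(t_max)) w_end <- min(w_end, t_max)
  win <- which(t > peak_t & t <= w_end)
  undershoot <- ahp_metric <- ahp_latency <- NA_real_
  if (length(win) > 0) {
    u_i <- win[which.min(v[win])]
    u_t <- t[u_i]
    undershoot <- v[u_i] - thr
    ahp_latency <- u_t - peak_t
    ahp_ok <- u_t + 1 <= max(t) &&
      (is.null(next_threshold_t) || next_threshold_t - u_t >= 1) &&
      (is.null(t_max) || u_t + 1 <= t_max)
    if (ahp_ok) ahp_metric <- interp_at(t, v, u_t + 1) - v[u_i]
  }

  tibble(
    threshold_mv = thr, threshold_t_ms = threshold$threshold_t,
    peak_mv = peak_v, peak_t_ms = peak_t, height_mv = height,
    halfwidth_ms = hw, overshoot_mv = peak_v,
    undershoot_mv = undershoot, ahp_metric_mv = ahp_metric,
    ahp_latency_ms = ahp_latency,
    max_dvdt_vps = threshold$d_max
  )
}

#' Extract features for every spike in a sweep
#'
#' Runs [detect_spikes()], [estimate_baseline_dvdt()] and, per spike,
#' [spike_threshold()] and [ap_features()], truncating each spike's
#' undershoot window at the next spike's threshold crossing and at
#' `step_offset`.
#'
#' @inheritParams detect_spikes
#' @param step_onset,step_offset Step epoch (ms); taken from the trace
#'   attributes when omitted.
#' @return Tibble with one row per spike (possibly empty).
#' @export
extract_spike_features <- function(trace, step_onset = NULL,
                                   step_offset = NULL, dvdt_threshold = 20,
                                   refractory = 1, window_ms = 10) {
  step_onset <- step_onset %||% attr(trace, "onset_ms") %||% min(trace$time_ms)
  step_offset <- step_offset %||% attr(trace, "offset_ms") %||%
    max(trace$time_ms)
  peaks <- detect_spikes(trace, dvdt_threshold, refractory)
  peaks <- peaks[trace$time_ms[peaks] >= step_onset &
                   trace$time_ms[peaks] <= step_offset]
  if (length(peaks) == 0L) return(tibble())
  baseline <- suppressWarnings(estimate_baseline_dvdt(
    trace, step_onset, first_spike_peak = trace$time_ms[peaks[1]],
    step_offset = step_offset, dvdt_threshold = dvdt_threshold
  ))
  thr <- map(peaks, function(p) spike_threshold(trace, p, baseline))
  thr_t <- map_dbl(thr, "threshold_t")
  bind_rows(imap(thr, function(th, k) {
    nxt <- if (k < length(peaks)) thr_t[k + 1] else NULL
    ap_features(trace, peaks[k], th, window_ms = window_ms,
                next_threshold_t = nxt, t_max = step_offset)
  }))
}
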