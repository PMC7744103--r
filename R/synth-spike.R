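# Closed-form action-potential template.
#
# The template is built from cosine-ease segments whose breakpoints are all
# available in closed form, so every feature the extractor measures (5%-of-
# peak-dV/dt threshold, halfwidth, undershoot, 1-ms AHP metric, AHP latency)
# is known by construction:
#
#   rest --(foot)--> V_start --(upstroke, half-cosine)--> peak
#        --(repolarization, half-cosine)--> threshold
#        --(descent, half-cosine)--> trough --(linear AHP recovery)--> ...
#
# On the half-cosine upstroke V(u) = V_start + A(1 - cos(pi u))/2, dV/dt is
# proportional to sin(pi u), so dV/dt rises through 5% of its peak exactly at
# u5 = asin(0.05)/pi; V_start is chosen so the voltage there equals the
# designed threshold. The foot's slope is capped at half the 5% level so the
# last upward 5% crossing always sits on the upstroke.

U5 <- asin(0.05) / pi
C5 <- (1 - cos(asin(0.05))) / 2

# Segment durations and anchor voltages for a designed spike. rate_of_rise in
# V/s (numerically mV/ms).
spike_design <- function(threshold_v, peak_v, halfwidth, undershoot_v,
                         ahp_metric, ahp_latency, rate_of_rise = 300) {
  if (halfwidth <= 0 || peak_v <= threshold_v) {
    abort("invalid spike parameters: need halfwidth > 0 and peak_v > threshold_v")
  }
  if (undershoot_v >= 0) abort("`undershoot_v` is relative to threshold and must be negative")
  if (ahp_metric < 0) abort("`ahp_metric` must be non-negative")
  v_start <- (threshold_v - C5 * peak_v) / (1 - C5)
  amp <- peak_v - v_start
  d_up <- amp * pi / (2 * rate_of_rise)
  v_half <- threshold_v + (peak_v - threshold_v) / 2
  u_h <- acos(1 - 2 * (v_half - v_start) / amp) / pi
  hw_up <- d_up * (1 - u_h)
  d_down1 <- 2 * (halfwidth - hw_up)
  if (d_down1 <= 0.02) {
    abort("halfwidth too small for the requested rate of rise")
  }
  d_rest <- ahp_latency - d_down1
  if (d_rest <= 0.02) {
    abort("ahp_latency too small for the requested halfwidth")
  }
  list(
    threshold_v = threshold_v, peak_v = peak_v, halfwidth = halfwidth,
    undershoot_v = undershoot_v, trough_v = threshold_v + undershoot_v,
    ahp_metric = ahp_metric, ahp_latency = ahp_latency,
    rate_of_rise = rate_of_rise,
    v_start = v_start, amp = amp,
    d_up = d_up, d_down1 = d_down1, d_rest = d_rest,
    thr_to_peak = d_up * (1 - U5),
    thr_to_trough = d_up * (1 - U5) + d_down1 + ahp_latency - d_down1
  )
}

# Voltage at time s (ms) after the designed threshold crossing; linear AHP
# recovery continues indefinitely beyond the trough (callers clip).
wave_from_threshold <- function(des, s) {
  v <- numeric(length(s))
  t1 <- des$thr_to_peak
  t2 <- t1 + des$d_down1
  t3 <- des$thr_to_trough
  seg <- findInterval(s, c(0, t1, t2, t3))
  i <- seg == 1L
  v[i] <- des$v_start + des$amp * (1 - cospi(U5 + s[i] / des$d_up)) / 2
  i <- seg == 2L
  v[i] <- des$threshold_v +
    (des$peak_v - des$threshold_v) * (1 + cospi((s[i] - t1) / des$d_down1)) / 2
  i <- seg == 3L
  v[i] <- des$trough_v +
    (des$threshold_v - des$trough_v) * (1 + cospi((s[i] - t2) / des$d_rest)) / 2
  i <- seg == 4L
  v[i] <- des$trough_v + des$ahp_metric * (s[i] - t3)
  v[seg == 0L] <- NA_real_
  v
}

#' Generate an analytic action-potential template
#'
#' Builds a piecewise-analytic voltage trace in which every waveform feature
#' has a closed-form location: the designed threshold sits exactly where
#' dV/dt rises through 5% of its peak, the width at half of the
#' threshold-to-peak amplitude equals `halfwidth`, the undershoot trough lies
#' `ahp_latency` after the peak at `threshold_v + undershoot_v`, and the
#' post-trough recovery is linear so the voltage 1 ms after the trough
#' exceeds it by exactly `ahp_metric`. Used to calibrate and validate the
#' feature extractor.
#'
#' @param threshold_v Designed spike threshold (mV).
#' @param peak_v Spike peak (mV, absolute; the overshoot when positive).
#' @param halfwidth Width at half amplitude, threshold to peak (ms).
#' @param undershoot_v Trough voltage relative to threshold (mV, negative).
#' @param ahp_metric Linear recovery over the 1 ms after the trough (mV).
#' @param ahp_latency Peak-to-trough delay (ms).
#' @param baseline_dvdt Constant drift (mV/ms) added to the pre-threshold
#'   segment, anchored at the threshold time so the designed
#'   post-subtraction threshold is unchanged.
#' @param rate_of_rise Peak dV/dt of the upstroke (V/s).
#' @param rest_v Baseline voltage (mV); must lie below the upstroke foot.
#' @param sampling_khz Sampling rate (kHz).
#' @param pre_ms Baseline padding before the foot (ms). The actual padding is
#'   nudged by less than one sample so the trough falls exactly on the grid.
#' @param recovery_ms Duration of the linear AHP recovery (ms, >= 1.2 so the
#'   1-ms metric is measurable).
#' @param post_ms Flat padding after the recovery (ms).
#' @return A tibble with `time_ms` and `voltage_mv`, carrying the design
#'   (segment times and true feature values) in attribute `"design"` and the
#'   sampling rate in `"sampling_khz"`.
#' @examples
#' tr <- make_analytic_spike(-43.46, 20.46, 0.55, -14.03, 1.55, 1.81)
#' attr(tr, "design")$threshold_t
#' @export
make_analytic_spike <- function(threshold_v, peak_v, halfwidth, undershoot_v,
                                ahp_metric, ahp_latency, baseline_dvdt = 0,
                                rate_of_rise = 300, rest_v = -65,
                                sampling_khz = 40, pre_ms = 5,
                                recovery_ms = 3, post_ms = 2) {
  des <- spike_design(threshold_v, peak_v, halfwidth, undershoot_v,
                      ahp_metric, ahp_latency, rate_of_rise)
  if (recovery_ms < 1.2) abort("`recovery_ms` must be at least 1.2 ms")
  if (rest_v >= des$v_start) {
    abort("`rest_v` must lie below the upstroke foot voltage")
  }
  dt <- 1 / sampling_khz
  # Foot: cosine ease rest -> v_start with peak slope at half the 5% level.
  d5 <- 0.05 * des$rate_of_rise
  d_foot <- (des$v_start - rest_v) * pi / (2 * 0.5 * d5)
  thr_raw <- pre_ms + d_foot + U5 * des$d_up
  trough_raw <- thr_raw + des$thr_to_trough
  pad <- ceiling(trough_raw / dt) * dt - trough_raw
  t_foot <- pre_ms + pad
  t_up <- t_foot + d_foot
  t_thr <- t_up + U5 * des$d_up
  t_trough <- t_thr + des$thr_to_trough
  total <- t_trough + recovery_ms + post_ms
  time <- seq(0, total, by = dt)

  v <- numeric(length(time))
  v[time < t_foot] <- rest_v
  i <- time >= t_foot & time < t_up
  v[i] <- rest_v + (des$v_start - rest_v) * (1 - cospi((time[i] - t_foot) / d_foot)) / 2
  i <- time >= t_up & time < t_thr
  v[i] <- des$v_start + des$amp * (1 - cospi((time[i] - t_up) / des$d_up)) / 2
  i <- time >= t_thr & time < t_trough + recovery_ms
  v[i] <- wave_from_threshold(des, time[i] - t_thr)
  i <- time >= t_trough + recovery_ms
  v[i] <- des$trough_v + des$ahp_metric * recovery_ms
  # Pre-threshold tilt, anchored at the threshold time.
  if (baseline_dvdt != 0) {
    i <- time <= t_thr
    v[i] <- v[i] + baseline_dvdt * (time[i] - t_thr)
  }

  out <- tibble(time_ms = time, voltage_mv = v)
  attr(out, "sampling_khz") <- sampling_khz
  attr(out, "design") <- c(des, list(
    threshold_t = t_thr, peak_t = t_thr + des$thr_to_peak,
    trough_t = t_trough, rest_v = rest_v, baseline_dvdt = baseline_dvdt
  ))
  out
}
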