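# Per-cell intrinsic-property profiles.

# Pull one sweep out of a long sweep-set tibble, keeping timing attributes.
sweep_trace <- function(sweepset, which_sweep) {
  tr <- filter(sweepset, .data$sweep == which_sweep)
  if (nrow(tr) == 0) abort(sprintf("no sweep %s in sweep set", which_sweep))
  out <- tibble(time_ms = tr$time_ms, voltage_mv = tr$voltage_mv,
                current_pa = tr$current_pa)
  attr(out, "sampling_khz") <- attr(sweepset, "sampling_khz")
  attr(out, "onset_ms") <- attr(sweepset, "onset_ms")
  attr(out, "offset_ms") <- attr(sweepset, "offset_ms")
  attr(out, "step_pa") <- tr$step_pa[1]
  out
}

#' Input resistance from a hyperpolarizing step (Ohm's law)
#'
#' `R_in = 1000 * dV / dI` MOhm, where `dV` (mV) is the mean voltage over
#' the last 20% of the step minus the mean over the `baseline_ms` preceding
#' onset, and `dI` (pA) is the step amplitude.
#'
#' @param sweep Tibble with `time_ms` and `voltage_mv`; step metadata read
#'   from attributes unless given.
#' @param step_pa,onset_ms,offset_ms Step descriptor (pA, ms).
#' @param baseline_ms Pre-onset baseline window (ms).
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(sweep, step_pa = NULL, onset_ms = NULL,
                             offset_ms = NULL, baseline_ms = 50) {
  step_pa <- step_pa %||% attr(sweep, "step_pa")
  onset_ms <- onset_ms %||% attr(sweep, "onset_ms")
  offset_ms <- offset_ms %||% attr(sweep, "offset_ms")
  if (is.null(step_pa) || is.null(onset_ms) || is.null(offset_ms)) {
    abort("step metadata (step_pa, onset_ms, offset_ms) is required")
  }
  if (step_pa == 0) abort("step amplitude is zero; R_in undefined")
  if (step_pa > 0) abort("R_in requires a hyperpolarizing (negative) step")
  if (length(detect_spikes(sweep)) > 0) {
    abort("sweep contains spikes; R_in measurement contaminated")
  }
  t <- sweep$time_ms
  v <- sweep$voltage_mv
  base <- v[t >= onset_ms - baseline_ms & t < onset_ms]
  step_len <- offset_ms - onset_ms
  plateau <- v[t >= offset_ms - 0.2 * step_len & t < offset_ms]
  if (length(base) == 0 || length(plateau) == 0) {
    abort("empty baseline or plateau window")
  }
  1000 * (mean(plateau) - mean(base)) / step_pa
}

#' Average firing rate at a target current step
#'
#' Spike count within the step epoch divided by step duration, averaged over
#' all sweeps at `target_step`.
#'
#' @param sweepset Long sweep tibble from [simulate_step_responses()] (or
#'   the same shape: `sweep`, `step_pa`, `time_ms`, `voltage_mv`).
#' @param target_step Step amplitude to analyse (pA); the published rates
#'   use +500 pA.
#' @param dvdt_threshold,refractory Passed to [detect_spikes()].
#' @return Firing rate (spikes/s).
#' @export
firing_rate <- function(sweepset, target_step = 500, dvdt_threshold = 20,
                        refractory = 1) {
  ids <- unique(sweepset$sweep[sweepset$step_pa == target_step])
  if (length(ids) == 0) {
    abort(sprintf("no sweep with a %+g pA step", target_step))
  }
  onset <- attr(sweepset, "onset_ms")
  offset <- attr(sweepset, "offset_ms")
  rates <- map_dbl(ids, function(k) {
    tr <- sweep_trace(sweepset, k)
    pk <- detect_spikes(tr, dvdt_threshold, refractory)
    tt <- tr$time_ms[pk]
    sum(tt >= onset & tt < offset) / (offset - onset) * 1000
  })
  mean(rates)
}

#' Build a cell's intrinsic-property profile
#'
#' Combines the published metric set for one cell: input resistance from the
#' designated (most negative) hyperpolarizing sweep, spike-shape features
#' averaged over the first `n_spikes` spikes of the lowest suprathreshold
#' step, and the firing rate at `rate_step`. Missing pieces (no
#' hyperpolarizing sweep, no +500 pA sweep, ...) yield `NA` fields and are
#' listed in the `flags` attribute rather than failing the profile.
#'
#' @inheritParams firing_rate
#' @param cell_id Cell label; defaults to the sweep-set attribute.
#' @param n_spikes Number of spikes entering the waveform averages
#'   (default: all spikes of the selected sweep).
#' @param rate_step Current step for the firing-rate metric (pA).
#' @return One-row tibble: `cell_id`, `rin_mohm`, `ap_height_mv`,
#'   `ap_halfwidth_ms`, `ahp_mv`, `ahp_latency_ms`, `rate_of_rise_vps`,
#'   `threshold_mv`, `overshoot_mv`, `undershoot_mv`, `firing_rate_hz`,
#'   `n_spikes_analyzed`; attribute `flags` lists missing measurements.
#' @export
build_intrinsic_profile <- function(sweepset, cell_id = NULL,
                                    n_spikes = Inf, rate_step = 500) {
  cell_id <- cell_id %||% attr(sweepset, "cell_id") %||% "cell"
  steps <- dplyr::distinct(sweepset[, c("sweep", "step_pa")])
  flags <- character()

  rin <- NA_real_
  hyp <- filter(steps, .data$step_pa < 0)
  if (nrow(hyp) == 0) {
    flags <- c(flags, "no hyperpolarizing sweep: R_in missing")
  } else {
    k <- hyp$sweep[which.min(hyp$step_pa)]
    rin <- tryCatch(input_resistance(sweep_trace(sweepset, k)),
                    error = function(e) {
                      flags <<- c(flags, conditionMessage(e))
                      NA_real_
                    })
  }

  feats <- tibble()
  for (k in arrange(filter(steps, .data$step_pa > 0), .data$step_pa)$sweep) {
    feats <- extract_spike_features(sweep_trace(sweepset, k))
    if (nrow(feats) > 0) break
  }
  if (nrow(feats) == 0) {
    flags <- c(flags, "no suprathreshold sweep with spikes")
    feats <- tibble(height_mv = NA_real_, halfwidth_ms = NA_real_,
                    ahp_metric_mv = NA_real_, ahp_latency_ms = NA_real_,
                    max_dvdt_vps = NA_real_, threshold_mv = NA_real_,
                    overshoot_mv = NA_real_, undershoot_mv = NA_real_)
    n_used <- 0L
  } else {
    n_used <- min(nrow(feats), n_spikes)
    feats <- head(feats, n_used)
  }

  rate <- tryCatch(firing_rate(sweepset, rate_step), error = function(e) {
    flags <<- c(flags, conditionMessage(e))
    NA_real_
  })

  m <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- tibble(
    cell_id = cell_id,
    rin_mohm = rin,
    ap_height_mv = m(feats$height_mv),
    ap_halfwidth_ms = m(feats$halfwidth_ms),
    ahp_mv = m(feats$ahp_metric_mv),
    ahp_latency_ms = m(feats$ahp_latency_ms),
    rate_of_rise_vps = m(feats$max_dvdt_vps),
    threshold_mv = m(feats$threshold_mv),
    overshoot_mv = m(feats$overshoot_mv),
    undershoot_mv = m(feats$undershoot_mv),
    firing_rate_hz = rate,
    n_spikes_analyzed = as.integer(n_used)
  )
  attr(out, "flags") <- flags
  out
}
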