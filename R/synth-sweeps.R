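# Current-clamp sweep generators.
#
# Spike *times* come from an exact leaky integrate-and-fire recursion: the
# membrane charges exponentially toward V_inf = V_rest + I*R_in, a spike is
# triggered at the closed-form crossing of the initiation voltage, the
# stereotyped analytic waveform (synth-spike.R) is spliced from the crossing
# to the end of its linear AHP recovery, and charging resumes from the
# recovery end-point. The recovery duration is calibrated once per
# phenotype/protocol so that the inter-spike interval at +500 pA equals
# 1/rate_at_500pA_true exactly; refractoriness emerges from the waveform and
# recovery durations. This decouples timing dynamics from waveform ground
# truth: both are exactly controllable.

# Time (ms) for exponential charging from v_from to v_t toward v_inf.
charge_time <- function(v_from, v_inf, v_t, tau) {
  if (v_inf <= v_t) return(Inf)
  if (v_from >= v_t) return(0)
  tau * log((v_inf - v_from) / (v_inf - v_t))
}

# Solve the linear-recovery duration so ISI(+500 pA) = 1000/rate (ms).
calibrate_recovery <- function(phen, des) {
  tau <- phen$r_in_true * phen$c_m / 1000
  v_inf <- phen$v_rest + 500 * phen$r_in_true / 1000
  target <- 1000 / phen$rate_at_500pa_true
  isi_at <- function(l) {
    v_end <- des$trough_v + des$ahp_metric * l
    des$thr_to_trough + l + charge_time(v_end, v_inf, phen$v_t, tau)
  }
  l_max <- if (des$ahp_metric > 0) {
    min(60, (phen$v_t - 0.5 - des$trough_v) / des$ahp_metric)
  } else 60
  if (l_max <= 1.05 || isi_at(1.05) > target || isi_at(l_max) < target) {
    abort(sprintf(
      "phenotype '%s' cannot be calibrated to %.1f sp/s at +500 pA",
      phen$name, phen$rate_at_500pa_true
    ))
  }
  uniroot(function(l) isi_at(l) - target, c(1.05, l_max), tol = 1e-10)$root
}

# Deterministic threshold-crossing times for one step current.
lif_spike_times <- function(phen, des, l_rec, step_pa, onset, offset) {
  tau <- phen$r_in_true * phen$c_m / 1000
  v_inf <- phen$v_rest + step_pa * phen$r_in_true / 1000
  t1 <- charge_time(phen$v_rest, v_inf, phen$v_t, tau)
  if (!is.finite(t1) || onset + t1 >= offset) return(numeric())
  v_end <- des$trough_v + des$ahp_metric * l_rec
  isi <- des$thr_to_trough + l_rec + charge_time(v_end, v_inf, phen$v_t, tau)
  times <- seq(onset + t1, offset, by = isi)
  times[times < offset]
}

#' Simulate current-step responses of a phenotype
#'
#' Generates one voltage sweep per step amplitude in `protocol`. Subthreshold
#' steps charge exponentially to a steady-state deflection of exactly
#' `step_pa * r_in_true / 1000` mV (Ohm's law); suprathreshold steps fire
#' trains whose +500 pA rate is calibrated to the phenotype's
#' `rate_at_500pa_true` and whose spike waveforms reproduce the phenotype's
#' shape parameters by construction. Spike-time jitter, when enabled, is
#' drawn per inter-spike interval with SD `jitter_growth * elapsed time`, so
#' jitter accumulates through the step as in chopper firing.
#'
#' @param phenotype A [sim_phenotype()].
#' @param protocol A [step_protocol()].
#' @param seed Integer seed (used only when jitter or noise is non-zero).
#' @param jitter_growth Jitter growth rate (ms/ms); defaults to the
#'   phenotype's value. Set to 0 for deterministic spike times.
#' @param noise_sd_mv SD of additive Gaussian measurement noise (mV).
#' @return A long tibble (`sweep`, `step_pa`, `time_ms`, `voltage_mv`,
#'   `current_pa`) with attributes `cell_id`, `protocol`, `sampling_khz`,
#'   `onset_ms`, `offset_ms` and `ground_truth` (per-sweep true spike
#'   threshold/peak times; never consumed by the analysis modules).
#' @export
simulate_step_responses <- function(phenotype, protocol, seed = NULL,
                                    jitter_growth = phenotype$jitter_growth,
                                    noise_sd_mv = 0) {
  stopifnot(inherits(phenotype, "sim_phenotype"),
            inherits(protocol, "step_protocol"))
  if (protocol$sampling_khz <= 0) abort("non-positive sampling rate")
  new_seeded_rng(seed)
  des <- spike_design(
    phenotype$threshold_true, phenotype$overshoot_true,
    phenotype$halfwidth_true, phenotype$undershoot_true,
    phenotype$ahp_metric_true, phenotype$ahp_latency_true,
    phenotype$rate_of_rise_true
  )
  l_rec <- if (phenotype$rate_at_500pa_true > 0) {
    calibrate_recovery(phenotype, des)
  } else 2
  onset <- protocol$onset_ms
  offset <- protocol$offset_ms
  w_dur <- des$thr_to_trough + l_rec

  sweeps <- imap(protocol$step_amplitudes, function(step_pa, k) {
    det <- lif_spike_times(phenotype, des, l_rec, step_pa, onset, offset)
    spikes <- det
    if (length(det) > 0 && jitter_growth > 0) {
      # Random-walk spike-time jitter whose variance budget makes the SD of
      # the k-th spike time exactly jitter_growth * (t_k - onset): jitter
      # accumulates through the step while per-interval increments stay
      # well below the ISI, preserving spike order and rate.
      tk <- det - onset
      inc_sd <- sqrt(pmax(jitter_growth^2 * diff(c(0, tk^2)), 0))
      inc_sd[1] <- max(inc_sd[1], 0.05)
      spikes <- sort(det + cumsum(rnorm(length(det), 0, inc_sd)))
      spikes <- spikes[spikes >= onset & spikes < offset]
      if (length(spikes) > 1) {
        keep <- c(TRUE, diff(spikes) > w_dur)
        spikes <- spikes[keep]
      }
    }
    tr <- render_step_sweep(phenotype, des, l_rec, step_pa, spikes, protocol)
    if (noise_sd_mv > 0) {
      tr$voltage_mv <- tr$voltage_mv + rnorm(nrow(tr), 0, noise_sd_mv)
    }
    tr$sweep <- k
    tr$step_pa <- step_pa
    list(
      trace = tr,
      truth = tibble(
        sweep = k, step_pa = step_pa,
        threshold_time_ms = spikes,
        peak_time_ms = spikes + des$thr_to_peak
      )
    )
  })

  out <- bind_rows(map(sweeps, "trace"))
  out <- out[, c("sweep", "step_pa", "time_ms", "voltage_mv", "current_pa")]
  attr(out, "cell_id") <- phenotype$name
  attr(out, "protocol") <- protocol
  attr(out, "sampling_khz") <- protocol$sampling_khz
  attr(out, "onset_ms") <- onset
  attr(out, "offset_ms") <- offset
  attr(out, "ground_truth") <- bind_rows(map(sweeps, "truth"))
  attr(out, "spike_design") <- c(des, list(l_rec = l_rec))
  out
}

# Render one sweep: exponential charging segments with spliced waveforms.
render_step_sweep <- function(phen, des, l_rec, step_pa, spikes, protocol) {
  dt <- 1 / protocol$sampling_khz
  tau <- phen$r_in_true * phen$c_m / 1000
  onset <- protocol$onset_ms
  offset <- protocol$offset_ms
  v_inf <- phen$v_rest + step_pa * phen$r_in_true / 1000
  time <- seq(0, protocol$duration_ms, by = dt)
  v <- rep(phen$v_rest, length(time))
  w_dur <- des$thr_to_trough + l_rec
  v_rec_end <- des$trough_v + des$ahp_metric * l_rec

  fill_charge <- function(v, a, b, v0, target) {
    i <- which(time >= a & time < b)
    if (length(i)) v[i] <- target + (v0 - target) * exp(-(time[i] - a) / tau)
    v
  }
  seg_start <- onset
  seg_v0 <- phen$v_rest
  for (s in spikes) {
    v <- fill_charge(v, seg_start, s, seg_v0, v_inf)
    i <- which(time >= s & time < s + w_dur)
    if (length(i)) v[i] <- wave_from_threshold(des, time[i] - s)
    seg_start <- s + w_dur
    seg_v0 <- v_rec_end
  }
  if (seg_start < offset) {
    v <- fill_charge(v, seg_start, offset, seg_v0, v_inf)
    v_off <- v_inf + (seg_v0 - v_inf) * exp(-(offset - seg_start) / tau)
    v <- fill_charge(v, offset, Inf, v_off, phen$v_rest)
  } else {
    # Last waveform runs past the step end; decay from its end-point.
    v <- fill_charge(v, seg_start, Inf, seg_v0, phen$v_rest)
  }
  tibble(
    time_ms = time, voltage_mv = v,
    current_pa = ifelse(time >= onset & time < offset, step_pa, 0)
  )
}

#' Simulate a passive (subthreshold) current-step sweep
#'
#' Mono-exponential charging with membrane time constant `tau_m` to a plateau
#' of `step_pa * r_in / 1000` mV, the Ohm's-law deflection used for input
#' resistance measurement.
#'
#' @param r_in Input resistance (MOhm).
#' @param tau_m Membrane time constant (ms).
#' @param step_pa Injected current (pA); hyperpolarizing steps are negative.
#' @param noise_sd SD of additive Gaussian voltage noise (mV).
#' @param seed Integer seed for the noise.
#' @param v_rest Resting potential (mV).
#' @param onset_ms,offset_ms,duration_ms,sampling_khz Protocol timing.
#' @return A tibble (`time_ms`, `voltage_mv`, `current_pa`) with attributes
#'   `sampling_khz`, `onset_ms`, `offset_ms`, `step_pa`.
#' @export
simulate_passive_sweep <- function(r_in, tau_m, step_pa, noise_sd = 0,
                                   seed = NULL, v_rest = -65,
                                   onset_ms = 100, offset_ms = 600,
                                   duration_ms = 700, sampling_khz = 40) {
  if (tau_m <= 0) abort("`tau_m` must be positive")
  check_number(r_in, "r_in", lower = 0, strict_lower = TRUE)
  new_seeded_rng(seed)
  dt <- 1 / sampling_khz
  time <- seq(0, duration_ms, by = dt)
  dv <- step_pa * r_in / 1000
  v <- rep(v_rest, length(time))
  i <- time >= onset_ms & time < offset_ms
  v[i] <- v_rest + dv * (1 - exp(-(time[i] - onset_ms) / tau_m))
  j <- time >= offset_ms
  v_off <- v_rest + dv * (1 - exp(-(offset_ms - onset_ms) / tau_m))
  v[j] <- v_rest + (v_off - v_rest) * exp(-(time[j] - offset_ms) / tau_m)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  out <- tibble(
    time_ms = time, voltage_mv = v,
    current_pa = ifelse(i, step_pa, 0)
  )
  attr(out, "sampling_khz") <- sampling_khz
  attr(out, "onset_ms") <- onset_ms
  attr(out, "offset_ms") <- offset_ms
  attr(out, "step_pa") <- step_pa
  out
}
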