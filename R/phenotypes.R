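#' Define a simulated intrinsic-property phenotype
#'
#' A phenotype bundles the ground-truth membrane and spike-shape parameters
#' used by [simulate_step_responses()]. The two presets carry the published
#' population means for the two glycinergic cell classes of the ventral
#' cochlear nucleus: the large D-stellate projection neuron and the small
#' local ("L") stellate interneuron.
#'
#' @param name Label for the phenotype.
#' @param c_m Membrane capacitance (pF).
#' @param r_in_true Input resistance (MOhm).
#' @param v_rest Resting potential with bias current (mV).
#' @param v_t Spike-initiation voltage of the integrate-and-fire timing model
#'   (mV). Defaults to `threshold_true` so spliced waveforms join the
#'   subthreshold trajectory continuously.
#' @param threshold_true Action-potential threshold of the stereotyped
#'   waveform (mV).
#' @param overshoot_true Spike peak relative to 0 mV (mV).
#' @param undershoot_true Undershoot trough relative to threshold (mV,
#'   negative).
#' @param halfwidth_true Spike width at half of the threshold-to-peak
#'   amplitude (ms).
#' @param ahp_metric_true Voltage rise over the 1 ms following the undershoot
#'   trough (mV, positive for a repolarizing recovery).
#' @param ahp_latency_true Delay from spike peak to undershoot trough (ms).
#' @param rate_of_rise_true Peak dV/dt of the spike upstroke (V/s).
#' @param rate_at_500pa_true Sustained firing rate at a +500 pA step
#'   (spikes/s).
#' @param jitter_growth Growth rate of spike-time jitter with elapsed step
#'   time (ms of SD per ms). The source recordings show accumulating chopper
#'   jitter but publish no rate, so this is a free parameter.
#' @return A list of class `sim_phenotype`.
#' @seealso [phenotype_preset()]
#' @export
sim_phenotype <- function(name,
                          c_m,
                          r_in_true,
                          v_rest = -65,
                          threshold_true,
                          v_t = threshold_true,
                          overshoot_true,
                          undershoot_true,
                          halfwidth_true,
                          ahp_metric_true,
                          ahp_latency_true,
                          rate_of_rise_true = 300,
                          rate_at_500pa_true,
                          jitter_growth = 0.004) {
  check_number(c_m, "c_m", lower = 0, strict_lower = TRUE)
  check_number(r_in_true, "r_in_true", lower = 0, strict_lower = TRUE)
  check_number(halfwidth_true, "halfwidth_true", lower = 0, strict_lower = TRUE)
  check_number(rate_at_500pa_true, "rate_at_500pa_true", lower = 0)
  check_number(jitter_growth, "jitter_growth", lower = 0)
  if (overshoot_true <= threshold_true) {
    abort("spike peak must exceed threshold")
  }
  if (undershoot_true >= 0) abort("`undershoot_true` is relative to threshold and must be negative")
  structure(
    list(
      name = name, c_m = c_m, r_in_true = r_in_true, v_rest = v_rest,
      v_t = v_t, threshold_true = threshold_true,
      overshoot_true = overshoot_true, undershoot_true = undershoot_true,
      spike_height_true = overshoot_true - threshold_true,
      halfwidth_true = halfwidth_true, ahp_metric_true = ahp_metric_true,
      ahp_latency_true = ahp_latency_true,
      rate_of_rise_true = rate_of_rise_true,
      rate_at_500pa_true = rate_at_500pa_true,
      jitter_growth = jitter_growth
    ),
    class = "sim_phenotype"
  )
}

#' Preset phenotypes carrying the published population means
#'
#' `"D_stellate"` and `"L_small"` carry the printed mean membrane properties
#' of, respectively, the D-stellate and the small glycinergic (L-stellate)
#' cells: input resistance, AP height/halfwidth, AHP metric and latency,
#' rate of rise, threshold, overshoot, undershoot, and the sustained firing
#' rate at +500 pA. Capacitance is not published; defaults give membrane time
#' constants of ~3-4 ms, typical of these cells.
#'
#' @param name `"D_stellate"` or `"L_small"`.
#' @param ... Overrides passed on to [sim_phenotype()].
#' @return A `sim_phenotype`.
#' @export
phenotype_preset <- function(name = c("D_stellate", "L_small"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    D_stellate = list(
      name = "D_stellate", c_m = 25, r_in_true = 114.87,
      threshold_true = -45.57, overshoot_true = 24.57,
      undershoot_true = -17.79, halfwidth_true = 0.31,
      ahp_metric_true = 4.18, ahp_latency_true = 0.87,
      rate_of_rise_true = 317.67, rate_at_500pa_true = 213.52
    ),
    L_small = list(
      name = "L_small", c_m = 12, r_in_true = 305.54,
      threshold_true = -43.46, overshoot_true = 20.46,
      undershoot_true = -14.03, halfwidth_true = 0.55,
      ahp_metric_true = 1.55, ahp_latency_true = 1.81,
      rate_of_rise_true = 288.06, rate_at_500pa_true = 225.72
    )
  )
  args <- utils::modifyList(base, list(...))
  do.call(sim_phenotype, args)
}

#' Define a current-step stimulus protocol
#'
#' @param step_amplitudes Injected step currents (pA), one sweep each.
#' @param onset_ms,offset_ms Step epoch (ms).
#' @param sampling_khz Sampling rate (kHz); recordings were digitized at
#'   20-40 kHz, so rates below 20 kHz are rejected.
#' @param duration_ms Sweep duration (ms).
#' @return A list of class `step_protocol`.
#' @export
step_protocol <- function(step_amplitudes = c(-300, 100, 500),
                          onset_ms = 100, offset_ms = 1100,
                          sampling_khz = 40, duration_ms = offset_ms + 200) {
  if (!is.numeric(step_amplitudes) || length(step_amplitudes) < 1L) {
    abort("`step_amplitudes` must be a numeric vector")
  }
  check_number(sampling_khz, "sampling_khz", lower = 0, strict_lower = TRUE)
  if (sampling_khz < 20) abort("`sampling_khz` must be at least 20 kHz")
  if (!(0 <= onset_ms && onset_ms < offset_ms && offset_ms <= duration_ms)) {
    abort("need 0 <= onset < offset <= duration")
  }
  structure(
    list(
      step_amplitudes = step_amplitudes, onset_ms = onset_ms,
      offset_ms = offset_ms, sampling_khz = sampling_khz,
      duration_ms = duration_ms
    ),
    class = "step_protocol"
  )
}

#' Define a synaptic event recording specification
#'
#' Describes the statistics of evoked and spontaneous postsynaptic currents
#' for [simulate_event_recording()]: stimulus-locked monosynaptic events
#' (latency < 1 ms), delayed polysynaptic events (latency > 2 ms),
#' spontaneous Poisson events, the difference-of-exponentials current kernel,
#' and how a pharmacological condition (e.g. carbachol) scales rates and
#' amplitudes.
#'
#' @param stim_times Stimulus times (ms).
#' @param mono_latency_mean,mono_latency_sd Monosynaptic latency (ms);
#'   the mean must be below 1 ms.
#' @param delayed_latency_mean,delayed_latency_sd Delayed-event latency (ms);
#'   the mean must exceed 2 ms.
#' @param mono_prob Release probability of the monosynaptic input per
#'   stimulus.
#' @param delayed_rate_per_stim Expected number of delayed events per
#'   stimulus.
#' @param spont_rate Spontaneous event rate (events/s).
#' @param amp_mean,amp_sd Event amplitude (pA).
#' @param tau_rise,tau_decay Kernel time constants (ms), `tau_decay >
#'   tau_rise > 0`.
#' @param noise_sd Baseline current noise SD (pA).
#' @param condition_rate_factor,condition_amp_factor Multipliers applied to
#'   delayed/spontaneous rates and to amplitudes under the treated condition.
#' @return A list of class `event_spec`.
#' @export
event_spec <- function(stim_times = numeric(),
                       mono_latency_mean = 0.7, mono_latency_sd = 0.05,
                       delayed_latency_mean = 4, delayed_latency_sd = 1,
                       mono_prob = 1, delayed_rate_per_stim = 0.5,
                       spont_rate = 3.566, amp_mean = 100, amp_sd = 20,
                       tau_rise = 0.2, tau_decay = 2, noise_sd = 0,
                       condition_rate_factor = 1.92,
                       condition_amp_factor = 1) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    abort("need tau_decay > tau_rise > 0")
  }
  if (mono_latency_mean >= 1) abort("`mono_latency_mean` must be below 1 ms")
  if (delayed_latency_mean <= 2) abort("`delayed_latency_mean` must exceed 2 ms")
  for (nm in c("mono_prob", "delayed_rate_per_stim", "spont_rate", "noise_sd")) {
    check_number(get(nm), nm, lower = 0)
  }
  structure(
    list(
      stim_times = sort(stim_times),
      mono_latency_mean = mono_latency_mean, mono_latency_sd = mono_latency_sd,
      delayed_latency_mean = delayed_latency_mean,
      delayed_latency_sd = delayed_latency_sd,
      mono_prob = mono_prob, delayed_rate_per_stim = delayed_rate_per_stim,
      spont_rate = spont_rate, amp_mean = amp_mean, amp_sd = amp_sd,
      tau_rise = tau_rise, tau_decay = tau_decay, noise_sd = noise_sd,
      condition_rate_factor = condition_rate_factor,
      condition_amp_factor = condition_amp_factor
    ),
    class = "event_spec"
  )
}

#' Define a synthetic morphology specification
#'
#' @param target_longest_axis,target_shortest_axis Caliper extents of the
#'   axonal-dendritic field in the reconstruction plane (um). The longest
#'   axis is the Feret diameter of the node set; the shortest is the minimal
#'   caliper width.
#' @param n_stems Number of primary neurites.
#' @param branch_depth Side branches grown per stem.
#' @param branch_radial_profile `"proximal-heavy"` places at least 60% of
#'   branch points within the inner third of the radial extent (as seen for
#'   the small glycinergic cells); `"distal-heavy"` mirrors the
#'   tufted, distally branching T-stellate pattern.
#' @param soma_radius Soma radius (um).
#' @return A list of class `morph_spec`.
#' @export
morph_spec <- function(target_longest_axis = 271.43,
                       target_shortest_axis = 148.60,
                       n_stems = 5, branch_depth = 3,
                       branch_radial_profile = c("proximal-heavy", "distal-heavy"),
                       soma_radius = 8) {
  branch_radial_profile <- match.arg(branch_radial_profile)
  if (!(target_longest_axis >= target_shortest_axis &&
        target_shortest_axis > 0)) {
    abort("need target_longest_axis >= target_shortest_axis > 0")
  }
  if (n_stems < 1) abort("`n_stems` must be at least 1")
  structure(
    list(
      target_longest_axis = target_longest_axis,
      target_shortest_axis = target_shortest_axis,
      n_stems = as.integer(n_stems), branch_depth = as.integer(branch_depth),
      branch_radial_profile = branch_radial_profile,
      soma_radius = soma_radius
    ),
    class = "morph_spec"
  )
}
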