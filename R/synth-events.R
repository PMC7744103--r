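# Synaptic event recording generator.

#' Unit-peak difference-of-exponentials synaptic kernel
#'
#' `k(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / k_peak` for `t >= 0`,
#' normalized so its maximum is 1; the peak time
#' `t_peak = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`
#' is closed-form.
#'
#' @param t Times since event onset (ms); values below 0 give 0.
#' @param tau_rise,tau_decay Time constants (ms), `tau_decay > tau_rise > 0`.
#' @return Kernel values.
#' @export
psc_kernel <- function(t, tau_rise, tau_decay) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    abort("need tau_decay > tau_rise > 0")
  }
  tp <- psc_kernel_peak_time(tau_rise, tau_decay)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- ifelse(t >= 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak, 0)
  out
}

#' @rdname psc_kernel
#' @export
psc_kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Simulate a synaptic-event current recording
#'
#' Builds a current trace as a sum of difference-of-exponentials events:
#' stimulus-locked monosynaptic events (one per stimulus with probability
#' `mono_prob`, latency drawn around `mono_latency_mean` < 1 ms), delayed
#' polysynaptic events (Poisson count per stimulus, latency >
#' 2 ms), and spontaneous Poisson events. Under `condition = "treated"` the
#' delayed and spontaneous rates are multiplied by `condition_rate_factor`
#' and amplitudes by `condition_amp_factor`, emulating carbachol's
#' recruitment of local collateral excitation. Ground-truth event times,
#' amplitudes and classes are stored alongside the trace and are never read
#' by the detection operators.
#'
#' @param spec An [event_spec()].
#' @param duration_ms Recording duration (ms).
#' @param condition `"control"` or `"treated"`.
#' @param seed Integer seed.
#' @param sampling_khz Sampling rate (kHz).
#' @return A tibble (`time_ms`, `current_pa`) with attributes
#'   `sampling_khz`, `stim_times`, `condition` and `ground_truth` (a tibble
#'   of true onset times, amplitudes and classes).
#' @export
simulate_event_recording <- function(spec, duration_ms,
                                     condition = c("control", "treated"),
                                     seed = NULL, sampling_khz = 10) {
  stopifnot(inherits(spec, "event_spec"))
  condition <- match.arg(condition)
  if (length(spec$stim_times) > 0 && duration_ms < max(spec$stim_times)) {
    abort("`duration_ms` is shorter than the last stimulus time")
  }
  new_seeded_rng(seed)
  rate_f <- if (condition == "treated") spec$condition_rate_factor else 1
  amp_f <- if (condition == "treated") spec$condition_amp_factor else 1

  events <- list()
  if (length(spec$stim_times) > 0) {
    fired <- runif(length(spec$stim_times)) < spec$mono_prob
    if (any(fired)) {
      lat <- rnorm(sum(fired), spec$mono_latency_mean, spec$mono_latency_sd)
      lat <- pmin(pmax(lat, 0.05), 0.95)
      events$mono <- tibble(
        time_ms = spec$stim_times[fired] + lat, class = "mono"
      )
    }
    n_del <- rpois(length(spec$stim_times), spec$delayed_rate_per_stim * rate_f)
    if (sum(n_del) > 0) {
      stim_rep <- rep(spec$stim_times, n_del)
      lat <- rnorm(sum(n_del), spec$delayed_latency_mean,
                   spec$delayed_latency_sd)
      lat <- pmax(lat, 2.1)
      events$delayed <- tibble(time_ms = stim_rep + lat, class = "delayed")
    }
  }
  n_spont <- rpois(1, spec$spont_rate * rate_f * duration_ms / 1000)
  if (n_spont > 0) {
    events$spont <- tibble(
      time_ms = sort(runif(n_spont, 0, duration_ms)), class = "spontaneous"
    )
  }
  truth <- bind_rows(events)
  if (nrow(truth) == 0) {
    truth <- tibble(time_ms = numeric(), class = character(),
                    amplitude_pa = numeric())
  } else {
    truth <- arrange(truth, .data$time_ms)
    truth$amplitude_pa <- pmax(
      rnorm(nrow(truth), spec$amp_mean, spec$amp_sd) * amp_f,
      spec$amp_mean * amp_f * 0.1
    )
    truth <- filter(truth, .data$time_ms < duration_ms)
  }

  dt <- 1 / sampling_khz
  time <- seq(0, duration_ms, by = dt)
  cur <- numeric(length(time))
  if (nrow(truth) > 0) {
    span <- psc_kernel_peak_time(spec$tau_rise, spec$tau_decay) +
      8 * spec$tau_decay
    n_k <- ceiling(span / dt)
    for (e in seq_len(nrow(truth))) {
      i0 <- floor(truth$time_ms[e] / dt) + 1L
      idx <- i0:min(i0 + n_k, length(time))
      cur[idx] <- cur[idx] + truth$amplitude_pa[e] *
        psc_kernel(time[idx] - truth$time_ms[e], spec$tau_rise, spec$tau_decay)
    }
  }
  if (spec$noise_sd > 0) cur <- cur + rnorm(length(cur), 0, spec$noise_sd)

  out <- tibble(time_ms = time, current_pa = cur)
  attr(out, "sampling_khz") <- sampling_khz
  attr(out, "stim_times") <- spec$stim_times
  attr(out, "condition") <- condition
  attr(out, "ground_truth") <- truth
  attr(out, "kernel") <- c(tau_rise = spec$tau_rise, tau_decay = spec$tau_decay)
  out
}
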