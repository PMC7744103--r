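# Spike-feature extraction against the analytic template's closed forms.

small_template <- function(...) {
  make_analytic_spike(-43.46, 20.46, 0.55, -14.03, 1.55, 1.81,
                      rate_of_rise = 288.06, ...)
}

test_that("spike detection finds the template apex and nothing on flat traces", {
  flat <- tibble::tibble(time_ms = seq(0, 100, by = 0.05),
                         voltage_mv = rep(-65, 2001))
  expect_length(detect_spikes(flat), 0)

  tr <- small_template()
  pk <- detect_spikes(tr)
  expect_length(pk, 1)
  expect_equal(tr$time_ms[pk], attr(tr, "design")$peak_t, tolerance = 0.03)
})

test_that("threshold follows the 5%-of-peak-dV/dt rule on designed templates", {
  tr <- small_template()
  th <- spike_threshold(tr, detect_spikes(tr))
  expect_equal(th$threshold_v, -43.46, tolerance = 0.1)

  d_tr <- make_analytic_spike(-45.57, 24.57, 0.31, -17.79, 4.18, 0.87,
                              rate_of_rise = 317.67)
  th_d <- spike_threshold(d_tr, detect_spikes(d_tr))
  expect_equal(th_d$threshold_v, -45.57, tolerance = 0.1)
})

test_that("threshold of a piecewise-linear spike matches the hand-computed crossing", {
  # Foot slope 1.6 mV/ms on [5, 7] ms, upstroke 40 mV/ms on [7, 8] ms, then
  # symmetric descent; dV/dt crosses 5% of its (central-difference) peak
  # within the corner sample at t = 7.
  dt <- 0.025
  t <- seq(0, 12, by = dt)
  v <- rep(-60, length(t))
  v[t > 5 & t <= 7] <- -60 + 1.6 * (t[t > 5 & t <= 7] - 5)
  v[t > 7 & t <= 8] <- -60 + 1.6 * 2 + 40 * (t[t > 7 & t <= 8] - 7)
  v[t > 8] <- pmax(-60, -60 + 1.6 * 2 + 40 - 40 * (t[t > 8] - 8))
  tr <- tibble::tibble(time_ms = t, voltage_mv = v)
  pk <- detect_spikes(tr)
  th <- spike_threshold(tr, pk)
  # Hand calculation: central-difference d_max = 40 at the interior of the
  # steep segment; d5 = 2. d at 6.975 is 1.6, at 7.0 is (1.6 + 40)/2 = 20.8;
  # interpolated crossing at 6.975 + (2 - 1.6)/(20.8 - 1.6) * 0.025.
  t_star <- 6.975 + (2 - 1.6) / (20.8 - 1.6) * 0.025
  v_star <- -60 + 1.6 * (t_star - 5)
  expect_equal(th$threshold_t, t_star, tolerance = 1e-9)
  expect_equal(th$threshold_v, v_star, tolerance = 1e-9)
})

test_that("a constant pre-spike tilt cancels exactly after baseline subtraction", {
  tr0 <- small_template()
  th0 <- spike_threshold(tr0, detect_spikes(tr0))
  tr2 <- small_template(baseline_dvdt = 2)
  base <- numeric(nrow(tr2))
  base[tr2$time_ms <= attr(tr2, "design")$threshold_t] <- 2
  th2 <- spike_threshold(tr2, detect_spikes(tr2), baseline = base)
  expect_equal(th2$threshold_v, th0$threshold_v, tolerance = 0.05)
})

test_that("baseline-subtraction invariance holds for fitted exponential drift", {
  tr <- small_template(pre_ms = 30)
  th0 <- spike_threshold(tr, detect_spikes(tr))
  # Add mono-exponential charging drift starting at t = 2 ms.
  drift_tau <- 8
  drift_amp <- 12
  tr2 <- tr
  onset <- 2
  i <- tr2$time_ms >= onset
  tr2$voltage_mv[i] <- tr2$voltage_mv[i] +
    drift_amp * (1 - exp(-(tr2$time_ms[i] - onset) / drift_tau))
  pk <- detect_spikes(tr2)
  est <- estimate_baseline_dvdt(tr2, step_onset = onset,
                                first_spike_peak = tr2$time_ms[pk])
  th2 <- spike_threshold(tr2, pk, baseline = est)
  # The detected crossing time is unchanged, so the threshold moves only by
  # the drift's value at that time (the trace genuinely sits higher there).
  expect_lt(abs(th2$threshold_t - th0$threshold_t), 0.1)
  drift_at <- drift_amp * (1 - exp(-(th0$threshold_t - onset) / drift_tau))
  expect_lt(abs(th2$threshold_v - (th0$threshold_v + drift_at)), 0.2)
})

test_that("baseline estimation recovers tau on passive sweeps and flags short windows", {
  sw <- simulate_passive_sweep(200, 10, -100, onset_ms = 100,
                               offset_ms = 600)
  est <- estimate_baseline_dvdt(sw, step_onset = 100, step_offset = 600)
  expect_equal(unname(attr(est, "fit")["tau"]), 10, tolerance = 0.02)
  expect_false(attr(est, "flagged"))

  expect_warning(
    short <- estimate_baseline_dvdt(sw, step_onset = 100,
                                    first_spike_peak = 101),
    "zero baseline"
  )
  expect_true(all(short == 0))
  expect_true(attr(short, "flagged"))
})

test_that("AP features match the template's designed values", {
  tr <- small_template()
  pk <- detect_spikes(tr)
  f <- ap_features(tr, pk, spike_threshold(tr, pk))
  expect_equal(f$halfwidth_ms, 0.55, tolerance = 0.05)
  expect_equal(f$ahp_metric_mv, 1.55, tolerance = 0.033)
  expect_equal(f$ahp_latency_ms, 1.81, tolerance = 0.02)
  expect_equal(f$undershoot_mv, -14.03, tolerance = 0.01)
  expect_equal(f$height_mv, 63.92, tolerance = 0.005)
  expect_equal(f$overshoot_mv, 20.46, tolerance = 0.005)
  expect_equal(f$max_dvdt_vps, 288.06, tolerance = 0.02)

  # Linear recovery of designed slope s gives ahp_metric = s x 1 ms.
  tr2 <- make_analytic_spike(-45, 20, 0.4, -12, 3.3, 1.2)
  pk2 <- detect_spikes(tr2)
  f2 <- ap_features(tr2, pk2, spike_threshold(tr2, pk2))
  expect_equal(f2$ahp_metric_mv, 3.3, tolerance = 0.02)
})

test_that("features agree between 20 and 40 kHz renderings", {
  tr40 <- small_template(sampling_khz = 40)
  tr20 <- small_template(sampling_khz = 20)
  f40 <- ap_features(tr40, detect_spikes(tr40),
                     spike_threshold(tr40, detect_spikes(tr40)))
  f20 <- ap_features(tr20, detect_spikes(tr20),
                     spike_threshold(tr20, detect_spikes(tr20)))
  expect_lt(abs(f40$halfwidth_ms - f20$halfwidth_ms), 0.05)
  expect_lt(abs(f40$threshold_mv - f20$threshold_mv), 0.2)
  expect_lt(abs(f40$undershoot_mv - f20$undershoot_mv), 0.2)
})

test_that("input resistance implements the exact mV/pA unit contract", {
  # Plateau of -11.487 mV at -100 pA must give 114.87 MOhm: 10^3 dV/dI.
  sw <- simulate_passive_sweep(114.87, 5, -100, onset_ms = 100,
                               offset_ms = 600)
  expect_equal(input_resistance(sw), 114.87, tolerance = 1e-4)

  sw2 <- simulate_passive_sweep(305.54, 15, -50)
  expect_equal(input_resistance(sw2), 305.54, tolerance = 0.01)

  expect_error(input_resistance(sw, step_pa = 0), "zero")
  expect_error(input_resistance(sw, step_pa = 100), "hyperpolarizing")
})

test_that("spiking sweeps are rejected for R_in measurement", {
  ss <- simulate_step_responses(phenotype_preset("L_small"),
                                step_protocol(c(100), sampling_khz = 20),
                                jitter_growth = 0)
  tr <- ss
  attr(tr, "step_pa") <- -100
  tr <- structure(tibble::tibble(time_ms = ss$time_ms,
                                 voltage_mv = ss$voltage_mv),
                  step_pa = -100, onset_ms = 100, offset_ms = 1100)
  expect_error(input_resistance(tr), "contaminated")
})

test_that("firing rate counts spikes over the step epoch", {
  phen <- phenotype_preset("L_small", rate_at_500pa_true = 200)
  prot <- step_protocol(c(500), onset_ms = 100, offset_ms = 600,
                        duration_ms = 700, sampling_khz = 20)
  ss <- simulate_step_responses(phen, prot, jitter_growth = 0)
  expect_equal(firing_rate(ss), 200, tolerance = 0.015)
  expect_error(firing_rate(ss, target_step = 250), "no sweep")
})

test_that("intrinsic profiles recover both phenotype presets end to end", {
  for (nm in c("L_small", "D_stellate")) {
    phen <- phenotype_preset(nm)
    ss <- simulate_step_responses(phen, recovery_protocol(), seed = 1,
                                  jitter_growth = 0)
    pr <- build_intrinsic_profile(ss)
    expect_equal(pr$rin_mohm, phen$r_in_true, tolerance = 0.02)
    expect_equal(pr$ap_halfwidth_ms, phen$halfwidth_true, tolerance = 0.02)
    expect_equal(pr$ap_height_mv, phen$spike_height_true, tolerance = 0.02)
    expect_lt(abs(pr$ahp_mv - phen$ahp_metric_true), 0.1)
    expect_equal(pr$firing_rate_hz, phen$rate_at_500pa_true,
                 tolerance = 0.02)
  }
})

test_that("profiles flag missing protocol pieces instead of failing", {
  ss <- simulate_step_responses(phenotype_preset("L_small"),
                                step_protocol(c(-300, 100), sampling_khz = 20),
                                jitter_growth = 0)
  pr <- build_intrinsic_profile(ss)
  expect_true(is.na(pr$firing_rate_hz))
  expect_false(is.na(pr$rin_mohm))
  expect_match(paste(attr(pr, "flags"), collapse = " "), "500")

  pr2 <- build_intrinsic_profile(ss)
  expect_equal(as.data.frame(pr), as.data.frame(pr2))
})
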