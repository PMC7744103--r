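# Synaptic-event detection, latency classification, condition effects,
# intervals and kinetics.

test_that("a single noise-free kernel is recovered exactly", {
  t <- seq(0, 200, by = 0.05)
  y <- 50 * psc_kernel(t - 20, 0.2, 5)
  tr <- tibble::tibble(time_ms = t, current_pa = y)
  ev <- detect_events(tr, tau_rise = 0.2, tau_decay = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_ms, 20)
  expect_equal(ev$amplitude_pa, 50, tolerance = 1e-9)
  expect_error(detect_events(tr, tau_rise = 5, tau_decay = 0.2), "tau_decay")
})

test_that("pure noise yields under one false event per minute at 4 SD", {
  total <- 0
  for (s in 1:2) {
    spec <- event_spec(spont_rate = 0, tau_rise = 0.5, tau_decay = 7.22,
                       noise_sd = 10)
    trn <- simulate_event_recording(spec, 60000, seed = 100 + s)
    total <- total + nrow(detect_events(trn))
  }
  expect_lte(total, 2)
})

test_that("detection on noise-free recordings reproduces ground truth", {
  spec <- event_spec(spont_rate = 2, tau_rise = 0.3, tau_decay = 3,
                     noise_sd = 0, amp_sd = 15)
  tr <- simulate_event_recording(spec, 20000, seed = 6)
  gt <- attr(tr, "ground_truth")
  ev <- detect_events(tr)
  expect_equal(nrow(ev), nrow(gt))
  # Events isolated by at least twice the detector's resolution are
  # recovered to sub-sample time accuracy and 2% amplitude accuracy;
  # closer pairs are resolved by matching pursuit but with degraded
  # amplitude attribution.
  sep <- psc_kernel_peak_time(0.3, 3) + 0.3
  isolated <- c(TRUE, diff(gt$time_ms) > 2 * sep) &
    c(diff(gt$time_ms) > 2 * sep, TRUE)
  m <- vapply(gt$time_ms[isolated],
              function(t0) min(abs(ev$time_ms - t0)), numeric(1))
  expect_true(all(m <= 0.1))
  amp_det <- vapply(gt$time_ms[isolated], function(t0) {
    ev$amplitude_pa[which.min(abs(ev$time_ms - t0))]
  }, numeric(1))
  expect_equal(amp_det, gt$amplitude_pa[isolated], tolerance = 0.02)
})

test_that("recall reaches 95% at SNR 5 on a 10 Hz spontaneous recording", {
  spec <- event_spec(spont_rate = 10, tau_rise = 0.3, tau_decay = 3,
                     amp_mean = 100, amp_sd = 20, noise_sd = 20)
  tr <- simulate_event_recording(spec, 30000, seed = 7)
  gt <- attr(tr, "ground_truth")
  ev <- detect_events(tr)
  m <- vapply(gt$time_ms, function(t0) min(abs(ev$time_ms - t0)), numeric(1))
  expect_gte(mean(m <= 1), 0.95)
})

test_that("latency classes follow the mono/delayed boundaries", {
  train <- tibble::tibble(time_ms = c(100.7, 102.5, 101.5, 150, 219.5))
  out <- evoked_latencies(train, stim_times = c(100, 200), window_ms = 20)
  expect_equal(out$latency_class,
               c("mono", "delayed", "unassigned", "spontaneous", "delayed"))
  expect_equal(out$latency_ms, c(0.7, 2.5, 1.5, NA, 19.5))

  none <- evoked_latencies(train, stim_times = numeric())
  expect_true(all(none$latency_class == "spontaneous"))
})

test_that("latency PSTHs conserve evoked counts and show designed modes", {
  spec <- event_spec(stim_times = seq(100, by = 100, length.out = 99),
                     mono_prob = 1, mono_latency_sd = 0.05,
                     delayed_rate_per_stim = 1, delayed_latency_mean = 5,
                     delayed_latency_sd = 0.5, spont_rate = 0,
                     tau_rise = 0.1, tau_decay = 0.8,
                     amp_mean = 300, amp_sd = 30, noise_sd = 15)
  tr <- simulate_event_recording(spec, 10000, seed = 8, sampling_khz = 40)
  ev <- evoked_latencies(detect_events(tr))
  h <- latency_psth(ev, bin = 1)
  expect_equal(sum(h$count), sum(!is.na(ev$latency_ms)))
  # Modes in the first (mono, < 1 ms) and the designed delayed bin.
  expect_gt(h$count[h$bin_start_ms == 0], 80)
  delayed_peak <- h$bin_start_ms[which.max(h$count * (h$bin_start_ms >= 2))]
  expect_true(delayed_peak %in% c(4, 5))

  empty <- latency_psth(evoked_latencies(tibble::tibble(time_ms = numeric()),
                                         stim_times = c(100)))
  expect_true(all(empty$count == 0))
})

test_that("condition change reproduces the printed percentage arithmetic", {
  # 25 -> 48 delayed events is a 92.0% increase.
  ctrl <- tibble::tibble(time_ms = seq_len(25),
                         latency_class = rep("delayed", 25))
  trt <- tibble::tibble(time_ms = seq_len(48),
                        latency_class = rep("delayed", 48))
  cc <- condition_change(ctrl, trt)
  expect_equal(cc$percent_increase, 92)

  same <- condition_change(ctrl, ctrl)
  expect_equal(same$percent_increase, 0)

  # Antisymmetry up to normalization: swapping conditions gives
  # -pct / (1 + pct/100).
  rev <- condition_change(trt, ctrl)
  expect_equal(rev$percent_increase, -92 / 1.92, tolerance = 1e-9)

  zero <- tibble::tibble(time_ms = numeric(), latency_class = character())
  expect_warning(out <- condition_change(list(zero), list(trt)), "zero")
  expect_true(is.nan(out$percent_increase) || is.na(out$percent_increase))
})

test_that("inter-event intervals and cumulative curves behave", {
  r <- interevent_intervals(c(0, 100, 300))
  expect_equal(r$iei_ms, c(100, 200))
  expect_equal(r$mean_ms, 150)
  expect_equal(max(r$cumulative$cum_prob), 1)

  expect_warning(empty <- interevent_intervals(c(5)), "fewer than 2")
  expect_equal(empty$n, 0L)

  # Poisson train: mean IEI ~ 1/rate; mean IEI x count ~ span.
  spec <- event_spec(spont_rate = 5, noise_sd = 0)
  tr <- simulate_event_recording(spec, 60000, seed = 9)
  gt <- attr(tr, "ground_truth")
  r2 <- interevent_intervals(gt$time_ms)
  expect_equal(r2$mean_ms, 200, tolerance = 0.1)
  expect_equal(r2$mean_ms * r2$n, diff(range(gt$time_ms)), tolerance = 1e-6)
})

test_that("decay tau is recovered across kernel speeds", {
  # Pure exponential decay: analytic recovery.
  t <- seq(0, 300, by = 0.05)
  y <- 80 * psc_kernel(t - 30, 0.2, 5)
  tr <- tibble::tibble(time_ms = t, current_pa = y)
  ev <- detect_events(tr, tau_rise = 0.2, tau_decay = 5)
  fit <- suppressWarnings(fit_decay_tau(tr, ev))
  expect_equal(fit$tau_ms, 5, tolerance = 0.01)

  # T-stellate sIPSC kernel (2.28 ms) at SNR 10.
  spec <- event_spec(spont_rate = 3, tau_rise = 0.25, tau_decay = 2.28,
                     amp_mean = 100, amp_sd = 20, noise_sd = 10)
  tr2 <- simulate_event_recording(spec, 30000, seed = 10)
  fit2 <- fit_decay_tau(tr2, detect_events(tr2))
  expect_equal(fit2$tau_ms, 2.28, tolerance = 0.05)

  # Bushy-cell sIPSC kernel (7.22 ms) at SNR 10, sparse firing.
  spec3 <- event_spec(spont_rate = 1, tau_rise = 0.5, tau_decay = 7.22,
                      amp_mean = 100, amp_sd = 20, noise_sd = 10)
  tr3 <- simulate_event_recording(spec3, 30000, seed = 11)
  fit3 <- fit_decay_tau(tr3, detect_events(tr3))
  expect_equal(fit3$tau_ms, 7.22, tolerance = 0.05)

  expect_error(fit_decay_tau(tr, ev[0, ]), "no events")
})
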