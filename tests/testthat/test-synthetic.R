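test_that("zero-rate configurations give empty trains and silent traces", {
  cfg <- event_train_config(rate = 0, amplitude_mean = 5)
  truth <- simulate_event_train(cfg, seed = 3)
  expect_equal(nrow(truth), 0)
  tr <- synthesize_trace(truth, cfg, noise_drift_config(noise_sd = 0, drift_amp = 0),
                         fs = 2, seed = 1)
  expect_true(all(tr$values == 0))
  expect_length(tr$values, cfg$duration_s * 2)
})

test_that("identical config and seed reproduce bit-identical outputs", {
  cfg <- event_train_config(rate = 4, amplitude_mean = 8, min_separation_s = 30)
  expect_identical(simulate_event_train(cfg, 11), simulate_event_train(cfg, 11))
  nz <- noise_drift_config(noise_sd = 0.3)
  t1 <- synthesize_trace(simulate_event_train(cfg, 11), cfg, nz, seed = 5)
  t2 <- synthesize_trace(simulate_event_train(cfg, 11), cfg, nz, seed = 5)
  expect_identical(t1, t2)
  tc <- trajectory_config(duration_s = 20, base_speed_mm_s = 1, dart_rate_per_min = 3)
  expect_identical(simulate_trajectory(tc, 7), simulate_trajectory(tc, 7))
})

test_that("event trains respect the minimum separation and stay in range", {
  cfg <- event_train_config(rate = 6, duration_s = 1800, min_separation_s = 60,
                            amplitude_mean = 5)
  for (s in 1:40) {
    truth <- simulate_event_train(cfg, s)
    expect_true(all(truth$amplitude > 0))
    expect_true(!is.unsorted(truth$event_time_s))
    expect_true(all(truth$event_time_s >= 0 & truth$event_time_s <= 1800))
    if (nrow(truth) >= 2) expect_true(all(diff(truth$event_time_s) >= 60))
  }
})

test_that("infeasible rate/separation combinations are rejected", {
  cfg <- event_train_config(rate = 20, duration_s = 1000, min_separation_s = 30,
                            amplitude_mean = 5)
  expect_error(simulate_event_train(cfg, 1), "separation")
})

test_that("planted event counts are Poisson-calibrated to the configured rate", {
  cfg <- event_train_config(rate = 3.46, duration_s = 1800, min_separation_s = 60,
                            amplitude_mean = 8)
  counts <- vapply(1:10000, function(s) nrow(simulate_event_train(cfg, s)), numeric(1))
  expect_lt(abs(mean(counts) - 3.46) / 3.46, 0.03)
})

test_that("a single planted event reproduces its amplitude at the kernel peak", {
  cfg <- event_train_config(rate = 1, amplitude_mean = 10, amplitude_sd = 0,
                            rise_tau_s = 2, decay_tau_s = 12)
  truth <- structure(data.frame(event_time_s = 600, amplitude = 10),
                     cfg = cfg, class = c("ground_truth", "data.frame"))
  tr <- synthesize_trace(truth, cfg, noise_drift_config(noise_sd = 0, drift_amp = 0),
                         fs = 2, seed = 1)
  expect_lt(abs(max(tr$values) - 10), 0.05)   # one-sample discretisation of the peak
})

test_that("additive noise has the configured standard deviation", {
  cfg <- event_train_config(rate = 0, amplitude_mean = 1)
  tr <- synthesize_trace(simulate_event_train(cfg, 1), cfg,
                         noise_drift_config(noise_sd = 2, drift_amp = 0),
                         fs = 2, seed = 42)
  expect_length(tr$values, 3600)
  expect_lt(abs(sd(tr$values) - 2), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(event_train_config(rate = -1, amplitude_mean = 5))
  expect_error(event_train_config(rate = 1, amplitude_mean = 5,
                                  rise_tau_s = 10, decay_tau_s = 5))
  expect_error(noise_drift_config(drift_period_s = 100), "drift_period")
  expect_error(synchrony_config(1.2, 0.5))
  expect_error(trajectory_config(base_speed_mm_s = 5, dart_speed_mm_s = 2))
})

test_that("preset calibration hits the printed statistics in expectation", {
  ## many-animal Monte Carlo against the three calibration targets of the
  ## control preset: detected count, detected amplitude, band power
  preset <- cohort_preset("control")
  n <- 60
  traces <- simulate_cohort_traces(preset, cohort_seeds(9, 0, n))
  filt <- lapply(traces, highpass_filter)
  thr <- derive_global_threshold(filt)
  met <- analyze_cohort_traces(traces, thr)
  expect_lt(abs(mean(met$count) - 1.67), 3.5 * sqrt(1.67 / n))
  expect_lt(abs(mean(met$mean_amplitude, na.rm = TRUE) - 3.94), 0.45)
  expect_lt(abs(mean(met$band_power) - 0.11), 0.05)
})

test_that("pipeline recovers planted events above twice the threshold", {
  ## >=95% sensitivity, timing error <= 1 sample, for clearly
  ## suprathreshold events of sufficient width
  ## timing jitter scales with noise over peak curvature, so the one-sample
  ## timing claim is checked at modest noise relative to the event size
  cfg <- event_train_config(rate = 5, duration_s = 1800, min_separation_s = 60,
                            amplitude_mean = 12, amplitude_sd = 1,
                            rise_tau_s = 2, decay_tau_s = 12)
  nz <- noise_drift_config(noise_sd = 0.05, drift_amp = 0.5)
  tp <- log(12 / 2) * 2 * 12 / 10        # kernel peak delay
  thr <- 3                                # planted amplitudes ~10 >= 2 x threshold
  planted <- 0; hits <- 0
  for (s in 1:25) {
    truth <- simulate_event_train(cfg, s)
    keep <- truth$event_time_s < 1790
    tr <- synthesize_trace(truth, cfg, nz, fs = 2, seed = s + 1000)
    ev <- detect_events(highpass_filter(tr), thr)
    for (t0 in truth$event_time_s[keep]) {
      planted <- planted + 1
      if (any(abs(ev$peak_time_s - (t0 + tp)) <= 0.5)) hits <- hits + 1
    }
  }
  expect_gte(hits / planted, 0.95)
})

test_that("trajectories are stationary, calibrated, and bounded", {
  tc0 <- trajectory_config(duration_s = 10, base_speed_mm_s = 0,
                           dart_rate_per_min = 0, dart_speed_mm_s = 1)
  tr0 <- simulate_trajectory(tc0, 1)
  expect_true(all(compute_velocity_series(tr0) == 0))
  tc <- trajectory_config(duration_s = 3600, base_speed_mm_s = 0.11,
                          dart_rate_per_min = 0)
  tr <- simulate_trajectory(tc, 2)
  m <- locomotion_metrics(tr)
  expect_lt(abs(m$mean_velocity_mm_s - 0.11), 0.005)
  expect_equal(m$darting_pct, 0)
  tcd <- trajectory_config(duration_s = 600, base_speed_mm_s = 2,
                           dart_rate_per_min = 6, dart_speed_mm_s = 40)
  trd <- simulate_trajectory(tcd, 3)
  expect_true(all(trd$x_mm^2 + trd$y_mm^2 <= tcd$arena_radius_mm^2 + 1e-9))
})
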