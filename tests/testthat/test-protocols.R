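# Protocol builders and experiment-level analyses.

test_that("theta-burst protocol has the canonical 5 x 10 structure", {
  p <- build_tbs()
  expect_length(p$pulse_times, 50L)
  expect_equal(p$pulse_times[1:5], c(0, 10, 20, 30, 40))
  onsets <- p$pulse_times[seq(1, 50, by = 5)]
  expect_equal(onsets, seq(0, 1800, by = 200))
  within <- unlist(lapply(split(p$pulse_times, rep(1:10, each = 5)), diff))
  expect_true(all(within == 10))
})

test_that("baseline and ramp protocols emit the documented sweep counts", {
  expect_length(build_baseline(100, duration_min = 20)$intensities, 120L)
  ramp <- build_io_ramp()
  expect_equal(ramp$intensities, seq(0, 320, by = 10))
  expect_equal(ramp$sweeps_per_level, 6)
})

test_that("input-output analysis recovers the recruitment curve", {
  p <- quiet_params(seed = 31)
  io <- analyze_io(simulate_experiment(p, build_io_ramp()))
  expect_equal(nrow(io$curve), 33L)
  expect_true(all(io$curve$n_sweeps == 6L))
  expect_equal(io$curve$mean_fv[io$curve$intensity == 320],
               fv_amplitude(p, 320), tolerance = 0.01)
  expect_true(all(diff(io$curve$mean_slope) >= -1e-9))

  hyp <- analyze_io(simulate_experiment(preset("hyperoxia", noise_sd = 0, seed = 31),
                                        build_io_ramp()))
  expect_gt(max(hyp$curve$mean_slope), max(io$curve$mean_slope))
  expect_gt(max(hyp$curve$mean_fv), max(io$curve$mean_fv))

  short <- simulate_experiment(p, build_io_ramp(sweeps_per_level = 2))
  expect_warning(analyze_io(short), "fewer than 6")
})

test_that("half-maximum targeting picks a mid-ramp intensity", {
  io <- analyze_io(simulate_experiment(quiet_params(seed = 2), build_io_ramp()))
  ih <- halfmax_intensity(io)
  expect_gt(ih, 30)
  expect_lt(ih, 200)
  slope_at <- io$curve$mean_slope[io$curve$intensity == ih]
  expect_equal(slope_at, 0.5 * max(io$curve$mean_slope), tolerance = 0.15)
})

test_that("paired-pulse ratio is 1 for identical responses and recovers f50", {
  # two identical constructed responses, fully separated
  sw <- pure_epsp_sweep(peak = 0.8, tau_r = 1, tau_d = 6, onset = 20)
  tm <- sweep_times(sw)
  sw$samples <- sw$samples - 0.8 * dualexp_ref(tm - 70 - 4, 1, 6)
  sw$stimulus_times <- c(20, 70)
  rec <- recording(list(sw), protocol = build_paired_pulse(100, n_sweeps = 1))
  expect_equal(analyze_ppr(rec)$ppr, 1.0, tolerance = 1e-6)

  for (f50 in c(1.0, 1.5, 2.0)) {
    p <- quiet_params(f50 = f50, seed = 17)
    rec <- simulate_experiment(p, build_paired_pulse(160, n_sweeps = 2))
    expect_equal(analyze_ppr(rec)$ppr, f50, tolerance = 0.01)
  }
})

test_that("noisy paired-pulse estimates stay near the generator value", {
  pprs <- vapply(1:5, function(s) {
    p <- sim_params(noise_sd = 0.05, f50 = 1.5, seed = s)
    analyze_ppr(simulate_experiment(p, build_paired_pulse(160, n_sweeps = 12)))$ppr
  }, numeric(1))
  expect_equal(mean(pprs), 1.5, tolerance = 0.05)
})

test_that("baseline stability statistic follows the binned-CV definition", {
  out <- check_baseline_stability(rep(0.2, 120), seq(0, 119) / 6)
  expect_equal(out$variance_pct, 0)
  expect_true(out$included)

  # alternating +/-20 % bins: CV hand-computed as 21.08 %
  slopes <- rep(rep(c(1.2, 0.8), 5), each = 6)
  times <- seq(0, length(slopes) - 1) / 6
  out <- check_baseline_stability(slopes, times)
  expect_equal(out$variance_pct, 21.08185, tolerance = 1e-4)
  expect_false(out$included)

  # additive offset drift does not move slopes, so drifting experiments pass
  for (s in 1:5) {
    p <- sim_params(drift_rate = 0.02, seed = s)
    rec <- simulate_experiment(p, build_baseline(160))
    meas <- measure_recording(rec)
    out <- check_baseline_stability(meas$epsp_slope, meas$t_acquired)
    expect_true(out$included)
  }

  expect_error(check_baseline_stability(rep(1, 5), 1:5 / 6), "at least 10")
  expect_error(check_baseline_stability(rep(1, 12), rep(0.01, 12)),
               "less than one")
})

test_that("exclusion is monotone in the baseline wobble", {
  base <- rep(rep(c(1.1, 0.9), 10), each = 6)
  times <- seq(0, length(base) - 1) / 6
  scaled_cv <- vapply(c(0.5, 1, 2, 4), function(k) {
    s <- 1 + (base - 1) * k
    check_baseline_stability(s, times)$variance_pct
  }, numeric(1))
  expect_true(all(diff(scaled_cv) > 0))
})

test_that("LTP normalization is exact and magnitude matches the closed form", {
  p <- quiet_params(p_ss = 1, a_ptp = 0, seed = 5)
  r <- analyze_ltp(simulate_experiment(p, build_ltp_protocol(160)))
  expect_equal(r$ltp_magnitude, 100, tolerance = 1e-6)
  base_bins <- r$timecourse$normalized_slope[r$timecourse$t_min < 0]
  expect_equal(mean(r$per_sweep$norm_slope[r$per_sweep$phase == "baseline"]),
               100, tolerance = 1e-12)
  expect_true(all(abs(base_bins - 100) < 1e-6))

  p2 <- quiet_params(p_ss = 2.0, tau_ltp = 5, seed = 5)
  r2 <- analyze_ltp(simulate_experiment(p2, build_ltp_protocol(160)))
  oracle <- 100 * potentiation_window_mean(2.0, 5, p2$a_ptp, p2$tau_ptp)
  expect_equal(r2$ltp_magnitude, oracle, tolerance = 0.02)

  cfg <- analysis_config(windows = list(ltp_window = c(80, 95)))
  expect_error(analyze_ltp(simulate_experiment(p2, build_ltp_protocol(160)),
                           cfg), "beyond the end")
})

test_that("tetanus depolarization is linear in gain and needs all bursts", {
  flat <- lapply(1:10, function(b) {
    sweep_trace(rep(0, 2000), stimulus_times = 20 + seq(0, 40, by = 10),
                sweep_index = b)
  })
  out <- tetanus_depolarization(flat)
  expect_equal(out$per_burst_auc, rep(0, 10))

  p1 <- quiet_params(seed = 3)
  p2 <- quiet_params(syn_gain = p1$syn_gain * 2, seed = 3)
  a1 <- tetanus_depolarization(
    simulate_experiment(p1, stimulus_protocol("tbs", intensities = 120)))
  a2 <- tetanus_depolarization(
    simulate_experiment(p2, stimulus_protocol("tbs", intensities = 120)))
  expect_equal(a2$mean_auc / a1$mean_auc, 2, tolerance = 0.01)

  expect_error(tetanus_depolarization(flat[1:7]), "found 7")
  expect_error(tetanus_depolarization(flat[1:7]), "8, 9, 10")
})

test_that("hyperoxia preset gives larger tetanus depolarization than air", {
  a <- tetanus_depolarization(
    simulate_experiment(preset("air", seed = 41),
                        stimulus_protocol("tbs", intensities = 120)))
  h <- tetanus_depolarization(
    simulate_experiment(preset("hyperoxia", seed = 41),
                        stimulus_protocol("tbs", intensities = 120)))
  expect_gt(h$mean_auc, a$mean_auc)
})
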