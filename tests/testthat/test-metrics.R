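# Per-sweep measurements against hand values, brute-force oracles, and
# invariance properties.

test_that("mCBI matches hand sums and a brute-force loop oracle", {
  expect_equal(as.numeric(compute_mcbi(flat_sweep(3))), 0)

  sw <- flat_sweep(0)
  sw$samples[251:255] <- c(0, 1, 0, 1, 0)  # t = 25.0 .. 25.4 ms
  expect_equal(as.numeric(compute_mcbi(sw, c(25, 25.4))), 4)
  expect_equal(attr(compute_mcbi(sw, c(25, 25.4)), "n_samples"), 5L)

  # element-by-element loop oracle on a simulated burst sweep, exact
  p <- preset("hyperoxia", seed = 21)
  rec <- simulate_experiment(p, stimulus_protocol("tbs", intensities = 120))
  for (sw in rec$sweeps[c(1, 5, 10)]) {
    tm <- sweep_times(sw)
    idx <- which(tm >= 25 - 1e-9 & tm <= 125 + 1e-9)
    acc <- 0
    for (i in idx[-length(idx)]) {
      acc <- acc + abs(sw$samples[i + 1] - sw$samples[i])
    }
    expect_equal(as.numeric(compute_mcbi(sw, c(25, 125))), acc,
                 tolerance = 1e-12)
  }
  expect_error(compute_mcbi(flat_sweep(), c(25, 25.05)), "fewer than 2")
  expect_error(compute_mcbi(flat_sweep(), c(150, 500)), "outside")
})

test_that("mCBI is offset-invariant, scales linearly, and grows with spikes", {
  p <- preset("hyperoxia", seed = 13)
  sw <- simulate_experiment(p, stimulus_protocol("tbs", intensities = 120))$sweeps[[3]]
  m0 <- as.numeric(compute_mcbi(sw))
  off <- sw; off$samples <- sw$samples + 3.7
  expect_equal(as.numeric(compute_mcbi(off)), m0, tolerance = 1e-12)
  sc <- sw; sc$samples <- sw$samples * -2.5
  expect_equal(as.numeric(compute_mcbi(sc)), 2.5 * m0, tolerance = 1e-12)

  base <- simulate_sweep(quiet_params(), 160)
  spiked <- base
  tm <- sweep_times(base)
  spiked$samples <- base$samples -
    0.3 * ifelse(tm > 40, ((tm - 40) / 0.3) * exp(1 - (tm - 40) / 0.3), 0)
  expect_gt(as.numeric(compute_mcbi(spiked)), as.numeric(compute_mcbi(base)))
})

test_that("stimulus onset detection uses annotation, threshold, and errors", {
  expect_equal(detect_stimulus_onset(flat_sweep(stim = 20)), 20)

  p <- quiet_params(stim_onset = 35)
  sw <- simulate_sweep(p, 100)
  sw$stimulus_times <- numeric()
  expect_equal(detect_stimulus_onset(sw), 35, tolerance = 0.1)

  hits <- vapply(1:100, function(s) {
    sw <- simulate_sweep(sim_params(noise_sd = 0.05, seed = s), 100,
                         seed = s)
    sw$stimulus_times <- numeric()
    detect_stimulus_onset(sw)
  }, numeric(1))
  expect_true(all(abs(hits - 20) <= 0.2))

  sw <- flat_sweep()
  sw$stimulus_times <- numeric()
  expect_error(detect_stimulus_onset(sw), "no stimulus artifact")
})

test_that("fiber volley measurement recovers the generator closed form", {
  expect_equal(measure_fiber_volley(simulate_sweep(quiet_params(), 0)), 0)

  p <- quiet_params(fv_max = 0.4, i_half = 50)  # A_fv(320) near 0.4
  sw <- simulate_sweep(p, 3200)
  expect_equal(measure_fiber_volley(sw), fv_amplitude(p, 3200),
               tolerance = 0.01)

  # recovered amplitudes follow the Hill recruitment curve
  p <- quiet_params()
  ints <- seq(10, 320, by = 10)
  rec <- vapply(ints, function(I) measure_fiber_volley(simulate_sweep(p, I)),
                numeric(1))
  truth <- fv_amplitude(p, ints)
  ss_res <- sum((rec - truth)^2)
  ss_tot <- sum((rec - mean(rec))^2)
  expect_gt(1 - ss_res / ss_tot, 0.99)
  expect_error(measure_fiber_volley(flat_sweep(), window = c(190, 210)),
               "outside")
})

test_that("initial slope matches linear and dense-grid chord oracles", {
  # constructed linear falling segment of slope -0.4 mV/ms
  sw <- flat_sweep()
  tm <- sweep_times(sw)
  ramp <- tm >= 25 & tm <= 35
  sw$samples[ramp] <- -0.4 * (tm[ramp] - 25)
  sw$samples[tm > 35] <- -0.4 * 10
  s <- measure_initial_slope(sw)
  expect_equal(as.numeric(s), 0.4, tolerance = 1e-6)

  sw2 <- sw; sw2$samples <- sw$samples * 2
  expect_equal(as.numeric(measure_initial_slope(sw2)), 0.8, tolerance = 1e-6)

  # dual-exponential rise: 20-80 % chord from a dense independent grid
  sw3 <- pure_epsp_sweep(peak = 1, tau_r = 2, tau_d = 20)
  chord <- local({
    tt <- seq(0, 10, by = 1e-4)
    y <- dualexp_ref(tt, 2, 20)
    t20 <- tt[min(which(y >= 0.2))]
    t80 <- tt[min(which(y >= 0.8))]
    0.6 / (t80 - t20)
  })
  expect_equal(chord, 0.3304329, tolerance = 1e-6)  # frozen oracle value
  expect_equal(as.numeric(measure_initial_slope(sw3)), chord, tolerance = 0.02)

  # offset invariance
  sw4 <- sw3; sw4$samples <- sw3$samples + 11
  expect_equal(as.numeric(measure_initial_slope(sw4)),
               as.numeric(measure_initial_slope(sw3)), tolerance = 1e-12)

  # too-coarse sampling is reported as a resolution problem
  coarse <- sweep_trace(
    -dualexp_ref((0:99) * 2 - 24, 2, 20),
    sample_interval = 2, stimulus_times = 20)
  expect_error(measure_initial_slope(coarse), "denser sampling")
})

test_that("AUC matches hand areas, an oversampled oracle, and is additive", {
  expect_equal(measure_auc(flat_sweep(2), start = 20, duration = 100), 0)

  sw <- flat_sweep()
  tm <- sweep_times(sw)
  sw$samples[tm >= 40 & tm < 90] <- -2     # 50 ms square deflection
  expect_equal(measure_auc(sw, start = 30, duration = 100), 100,
               tolerance = 0.01)

  # noise-free burst vs 100x oversampled trapezoid of the closed form
  p <- quiet_params(artifact_amp = 0)
  burst <- 20 + seq(0, 40, by = 10)
  sw2 <- simulate_sweep(p, 160, pulse_times = burst)
  a_fv <- fv_amplitude(p, 160)
  fac <- facilitation_factors(p, burst)
  tt <- seq(20, 120, by = 0.001)
  v <- rep(0, length(tt))
  alpha <- function(t, tau) ifelse(t > 0, (t / tau) * exp(1 - t / tau), 0)
  for (k in seq_along(burst)) {
    v <- v - a_fv * alpha(tt - burst[k] - p$fv_latency, p$fv_tau) -
      p$syn_gain * a_fv * fac[k] *
        dualexp_ref(tt - burst[k] - p$epsp_latency, p$tau_rise, p$tau_decay)
  }
  y <- pmax(0, -v)
  oracle <- sum((y[-1] + y[-length(y)]) / 2) * 0.001
  expect_equal(measure_auc(sw2, start = 20, duration = 100), oracle,
               tolerance = 0.005)

  # additivity up to the shared boundary sample
  whole <- measure_auc(sw2, start = 20, duration = 100)
  parts <- measure_auc(sw2, start = 20, duration = 50) +
    measure_auc(sw2, start = 70, duration = 50)
  expect_equal(parts, whole, tolerance = 0.01)

  expect_error(measure_auc(flat_sweep(), start = 150, duration = 100),
               "exceeds")
})

test_that("normalization divides by a positive reference", {
  expect_equal(normalize_metric(c(2, 2, 2), 2), c(1, 1, 1))
  expect_equal(normalize_metric(c(2, 4), 2), c(1, 2))
  v <- c(1.2, 0.8, 1.1, 0.9)
  expect_equal(mean(normalize_metric(v, mean(v))), 1)
  expect_error(normalize_metric(1:3, 0), "positive")
  expect_error(normalize_metric(1:3, -2), "positive")
})

test_that("noise-free metrics recover generator quantities for both presets", {
  for (cond in c("air", "hyperoxia")) {
    p <- preset(cond, noise_sd = 0, popspike_rate = 0)
    sw <- simulate_sweep(p, 320)
    expect_equal(measure_fiber_volley(sw), fv_amplitude(p, 320),
                 tolerance = 0.01)
    m <- measure_sweep(sw)
    expect_equal(m$epsp_amplitude, p$syn_gain * fv_amplitude(p, 320),
                 tolerance = 0.01)
  }
})
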