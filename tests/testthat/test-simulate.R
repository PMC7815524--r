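# Generative model: closed forms, determinism, calibration properties.

test_that("parameter validation rejects degenerate kinetics", {
  expect_error(sim_params(tau_rise = 20, tau_decay = 2), "tau_rise")
  expect_error(sim_params(tau_rise = 5, tau_decay = 5), "tau_rise")
  expect_error(sim_params(fv_tau = -1), "time constants")
  expect_error(sim_params(hill = 0), "hill")
  expect_error(sim_params(noise_sd = -0.1), "noise_sd")
  expect_error(sim_params(f50 = 0.8), "f50")
  expect_error(preset("vacuum"))
})

test_that("zero intensity leaves only the stimulus artifact", {
  p <- quiet_params()
  sw <- simulate_sweep(p, 0)
  tm <- sweep_times(sw)
  artifact <- p$artifact_amp * ifelse(tm >= 20, exp(-(tm - 20) / 0.1), 0)
  expect_equal(sw$samples, artifact, tolerance = 1e-12)
  expect_equal(fv_amplitude(p, 0), 0)
})

test_that("identical seeds give bit-identical sweeps and recordings", {
  p <- sim_params(popspike_rate = 1, seed = 77)
  a <- simulate_sweep(p, 150, seed = 123)
  b <- simulate_sweep(p, 150, seed = 123)
  expect_identical(a$samples, b$samples)
  c <- simulate_sweep(p, 150, seed = 124)
  expect_false(identical(a$samples, c$samples))

  r1 <- simulate_experiment(p, build_paired_pulse(100, n_sweeps = 4))
  r2 <- simulate_experiment(p, build_paired_pulse(100, n_sweeps = 4))
  expect_identical(lapply(r1$sweeps, `[[`, "samples"),
                   lapply(r2$sweeps, `[[`, "samples"))
})

test_that("a noise-free single-pulse sweep equals the closed-form sum", {
  # oracle written out independently of the implementation
  p <- quiet_params(fv_max = 0.4, i_half = 90, hill = 2, syn_gain = 2.5,
                    f50 = 1.4, drift_rate = 0.01)
  I <- 130
  t_acq <- 7
  sw <- simulate_sweep(p, I, t_acquired = t_acq)
  tm <- sweep_times(sw)
  a_fv <- 0.4 * I^2 / (I^2 + 90^2)
  alpha <- function(t, tau) ifelse(t > 0, (t / tau) * exp(1 - t / tau), 0)
  oracle <- 0.01 * t_acq +
    p$artifact_amp * ifelse(tm >= 20, exp(-(tm - 20) / 0.1), 0) -
    a_fv * alpha(tm - 20 - p$fv_latency, p$fv_tau) -
    2.5 * a_fv * dualexp_ref(tm - 20 - p$epsp_latency, p$tau_rise, p$tau_decay)
  expect_equal(sw$samples, oracle, tolerance = 1e-12)
})

test_that("recruitment is monotone and the response is linear in gain", {
  p <- quiet_params()
  ints <- seq(0, 320, by = 10)
  afv <- fv_amplitude(p, ints)
  expect_true(all(diff(afv) > 0))
  peaks <- vapply(ints, function(I) -min(simulate_sweep(p, I)$samples),
                  numeric(1))
  expect_true(all(diff(peaks) >= -1e-12))

  p2 <- quiet_params(syn_gain = p$syn_gain * 2)
  s1 <- simulate_sweep(p, 160)
  s2 <- simulate_sweep(p2, 160)
  epsp_zone <- sweep_times(s1) > 29  # past artifact and fiber volley
  expect_equal(s2$samples[epsp_zone], 2 * s1$samples[epsp_zone],
               tolerance = 1e-8)
  cfg <- analysis_config()
  expect_equal(measure_fiber_volley(s2, config = cfg),
               measure_fiber_volley(s1, config = cfg), tolerance = 1e-10)
  # one boundary sample can enter/leave the 20-80 % band under scaling
  expect_equal(as.numeric(measure_initial_slope(s2, config = cfg)),
               2 * as.numeric(measure_initial_slope(s1, config = cfg)),
               tolerance = 1e-3)
})

test_that("paired-pulse facilitation is exactly f50 at 50 ms when responses separate", {
  # fast kinetics so the first response fully decays before the second pulse
  for (f50 in c(1.0, 1.25, 1.5, 2.0)) {
    p <- quiet_params(f50 = f50, tau_rise = 0.4, tau_decay = 2,
                      artifact_amp = 0, epsp_latency = 10)
    sw <- simulate_sweep(p, 160, pulse_times = c(20, 70))
    tm <- sweep_times(sw)
    pk1 <- -min(sw$samples[tm > 24 & tm < 45])
    pk2 <- -min(sw$samples[tm > 74 & tm < 95])
    expect_equal(pk2 / pk1, f50, tolerance = 1e-9)
  }
})

test_that("facilitation kernel hits f50 at 50 ms and relaxes to 1", {
  p <- quiet_params(f50 = 1.5, tau_f = 250)
  expect_equal(facilitation_factors(p, c(0, 50))[2], 1.5)
  expect_lt(abs(facilitation_factors(p, c(0, 5000))[2] - 1), 1e-8)
  expect_gt(facilitation_factors(p, c(0, 10))[2], 1.5)  # shorter gap, more
})

test_that("condition presets differ only where the biology says they do", {
  air <- preset("air")
  hyp <- preset("hyperoxia")
  expect_identical(air$f50, hyp$f50)
  expect_gt(hyp$p_ss, air$p_ss)
  expect_gt(hyp$fv_max, air$fv_max)
  expect_gt(hyp$syn_gain, air$syn_gain)
  expect_identical(air$popspike_rate, 0)
  expect_gt(hyp$popspike_rate, 0)
  same <- setdiff(names(air), c("fv_max", "syn_gain", "p_ss", "popspike_rate"))
  expect_identical(air[same], hyp[same])
})

test_that("experiment layouts have the protocol-defined sweep counts", {
  p <- sim_params(seed = 5)
  io <- simulate_experiment(p, build_io_ramp())
  expect_length(io$sweeps, 33 * 6)
  expect_equal(length(unique(vapply(io$sweeps, `[[`, numeric(1),
                                    "stimulus_intensity"))), 33L)

  ltp <- simulate_experiment(p, build_ltp_protocol(100))
  phase <- vapply(ltp$sweeps, function(s) s$meta$phase, character(1))
  expect_equal(sum(phase == "baseline"), 120L)
  expect_equal(sum(phase == "tbs"), 10L)
  expect_equal(sum(phase == "followup"), 360L)

  weird <- stimulus_protocol("baseline", intensities = 100)
  weird$kind <- "triple_pulse"
  expect_error(simulate_experiment(p, weird), "unsupported protocol kind")
})

test_that("null potentiation leaves follow-up responses at baseline level", {
  p <- quiet_params(p_ss = 1, a_ptp = 0, drift_rate = 0, seed = 8)
  rec <- simulate_experiment(p, build_ltp_protocol(100))
  phase <- vapply(rec$sweeps, function(s) s$meta$phase, character(1))
  base <- rec$sweeps[phase == "baseline"][[1]]
  post <- rec$sweeps[phase == "followup"][[300]]
  expect_equal(min(post$samples), min(base$samples), tolerance = 1e-9)
})
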