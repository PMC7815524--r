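# Fixture builders shared across the suite. Everything is generated in code;
# voltages mV, times ms.

`%||%` <- function(a, b) if (is.null(a)) b else a

# noise-free generator parameters
quiet_params <- function(...) sim_params(noise_sd = 0, ...)

# sweep of constant voltage with an annotated stimulus
flat_sweep <- function(value = 0, n = 2000, stim = 20) {
  sweep_trace(rep(value, n), stimulus_times = stim)
}

# normalized dual-exponential rise/decay, zero before onset (independent of
# the package's internal shape helpers)
dualexp_ref <- function(t, tau_r, tau_d) {
  tpk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  pk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  ifelse(t > 0, (exp(-t / tau_d) - exp(-t / tau_r)) / pk, 0)
}

# sweep holding a pure dual-exponential fEPSP (no artifact, no fiber volley)
pure_epsp_sweep <- function(peak = 1, tau_r = 2, tau_d = 20, onset = 20,
                            latency = 4, n = 2000, si = 0.1) {
  tm <- (seq_len(n) - 1L) * si
  v <- -peak * dualexp_ref(tm - onset - latency, tau_r, tau_d)
  sweep_trace(v, sample_interval = si, stimulus_times = onset)
}

# closed-form average of the potentiation time course over the sweep times
# falling in [w1, w2] min post-tetanus (independent oracle for LTP recovery)
potentiation_window_mean <- function(p_ss, tau_ltp, a_ptp, tau_ptp,
                                     w = c(44, 59), dt_min = 1 / 6) {
  tt <- seq(dt_min, 60, by = dt_min)
  tt <- tt[tt >= w[1] & tt <= w[2]]
  mean(1 + (p_ss - 1) * (1 - exp(-tt / tau_ltp)) + a_ptp * exp(-tt / tau_ptp))
}
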