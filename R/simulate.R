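# Seeded generative model of extracellular field-potential sweeps.
#
# Each sweep is built from closed-form components on the sample grid:
#   V(t) = drift + artifact(t) + fiber volley(t) + fEPSP(t) + population
#          spikes(t) + Gaussian noise,
# where per pulse k at time t_k the fiber-volley amplitude follows a Hill
# recruitment curve of stimulus current, the fiber volley is a negative
# alpha function, the fEPSP a normalized dual exponential whose peak scales
# with recruitment, paired-pulse facilitation and (after a tetanus)
# potentiation, and successive responses sum linearly.

ARTIFACT_TAU <- 0.1   # ms, decay of the stimulus-artifact transient
POPSPIKE_TAU <- 0.3   # ms, width parameter of a population spike

#' Generative parameters for synthetic sweeps
#'
#' All voltages are mV, times within a sweep ms, currents uA, experiment
#' times min. Defaults describe a healthy control slice; see [preset()] for
#' the two study conditions.
#'
#' @param fv_max Maximal fiber-volley amplitude (mV).
#' @param i_half Half-recruitment current (uA) of the Hill curve.
#' @param hill Recruitment steepness (dimensionless, > 0).
#' @param fv_latency,fv_tau Fiber-volley onset latency and alpha-function
#'   time constant (ms); the volley peaks `fv_latency + fv_tau` after the pulse.
#' @param syn_gain Synaptic gain: fEPSP peak magnitude per mV of fiber volley.
#' @param epsp_latency fEPSP onset latency after the pulse (ms).
#' @param tau_rise,tau_decay Dual-exponential fEPSP kinetics (ms);
#'   `tau_rise < tau_decay` is required.
#' @param f50 Paired-pulse facilitation factor at a 50 ms interval
#'   (second/first response ratio; 1 = none).
#' @param tau_f Facilitation decay constant (ms).
#' @param p_ss Steady-state potentiation factor after tetanus (1 = no LTP).
#' @param tau_ltp LTP expression time constant (min).
#' @param a_ptp,tau_ptp Post-tetanic transient amplitude (dimensionless) and
#'   decay (min).
#' @param popspike_rate Expected population spikes per response (Poisson).
#' @param popspike_amp Population-spike amplitude (mV).
#' @param noise_sd Gaussian noise standard deviation (mV).
#' @param drift_rate Additive baseline drift (mV per min of experiment time).
#' @param artifact_amp Stimulus-artifact amplitude (mV).
#' @param stim_onset Stimulus time within a sweep (ms).
#' @param sweep_duration Sweep length (ms).
#' @param sample_interval Sampling interval (ms; default 0.1, i.e. 10 kHz).
#' @param seed Integer seed for the recording-level random stream.
#' @return An object of class `fieldlab_simparams`.
#' @export
sim_params <- function(fv_max = 0.30, i_half = 80, hill = 1.8,
                       fv_latency = 0.7, fv_tau = 0.3,
                       syn_gain = 2.0, epsp_latency = 4.0,
                       tau_rise = 2.0, tau_decay = 20.0,
                       f50 = 1.5, tau_f = 250,
                       p_ss = 1.34, tau_ltp = 5, a_ptp = 0.8, tau_ptp = 2,
                       popspike_rate = 0, popspike_amp = 0.30,
                       noise_sd = 0.02, drift_rate = 0.002,
                       artifact_amp = 5, stim_onset = 20,
                       sweep_duration = 200, sample_interval = 0.1,
                       seed = 1L) {
  p <- as.list(environment())
  taus <- c(fv_tau = fv_tau, tau_rise = tau_rise, tau_decay = tau_decay,
            tau_f = tau_f, tau_ltp = tau_ltp, tau_ptp = tau_ptp)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("all time constants must be positive and finite", call. = FALSE)
  }
  if (tau_rise >= tau_decay) {
    stop("degenerate kinetics: 'tau_rise' must be smaller than 'tau_decay'",
         call. = FALSE)
  }
  if (hill <= 0) stop("'hill' must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (f50 < 1) stop("'f50' must be >= 1 in the facilitating regime", call. = FALSE)
  if (p_ss <= 0 || popspike_rate < 0) {
    stop("'p_ss' must be > 0 and 'popspike_rate' >= 0", call. = FALSE)
  }
  structure(p, class = "fieldlab_simparams")
}

#' @export
print.fieldlab_simparams <- function(x, ...) {
  cat("<fieldlab_simparams>\n")
  flat <- unlist(x)
  cat(paste(sprintf("  %s = %g", names(flat), flat), collapse = "\n"), "\n")
  invisible(x)
}

#' Condition presets for the two exposure groups
#'
#' The `"hyperoxia"` preset differs from `"air"` only in larger maximal
#' fiber-volley recruitment, larger synaptic gain, larger steady-state
#' potentiation, and a nonzero population-spike rate; the facilitation
#' factor `f50` is identical across conditions (paired-pulse facilitation
#' does not differ between groups).
#'
#' @param condition `"air"` or `"hyperoxia"`.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A [sim_params()] object.
#' @export
#' @examples
#' preset("air")$f50 == preset("hyperoxia")$f50
preset <- function(condition = c("air", "hyperoxia"), ...) {
  condition <- match.arg(condition)
  over <- list(...)
  base <- switch(condition,
    air = list(fv_max = 0.30, syn_gain = 2.0, p_ss = 1.34, popspike_rate = 0),
    hyperoxia = list(fv_max = 0.55, syn_gain = 3.0, p_ss = 2.17,
                     popspike_rate = 1.5)
  )
  base[names(over)] <- over
  do.call(sim_params, base)
}

#' Hill recruitment: fiber-volley amplitude vs stimulus current
#'
#' @param params A [sim_params()] object.
#' @param intensity Stimulus current(s) in uA.
#' @return Fiber-volley amplitude(s) in mV:
#'   `fv_max * I^hill / (I^hill + i_half^hill)`.
#' @export
fv_amplitude <- function(params, intensity) {
  ih <- intensity^params$hill
  out <- params$fv_max * ih / (ih + params$i_half^params$hill)
  out[intensity <= 0] <- 0
  out
}

#' Facilitation factors for a pulse train
#'
#' Each pulse after the first is scaled by
#' `F = 1 + (f50 - 1) * exp(-(dt - 50) / tau_f)` where `dt` is the interval
#' to the preceding pulse (ms), so `F` equals `f50` exactly at `dt = 50` and
#' tends to 1 as `dt` grows.
#'
#' @param params A [sim_params()] object.
#' @param pulse_times Pulse times in ms (increasing).
#' @return One multiplicative factor per pulse (the first is 1).
#' @export
facilitation_factors <- function(params, pulse_times) {
  n <- length(pulse_times)
  f <- rep(1, n)
  if (n > 1L) {
    dt <- diff(pulse_times)
    f[-1L] <- 1 + (params$f50 - 1) * exp(-(dt - 50) / params$tau_f)
  }
  f
}

#' Potentiation time course after a tetanus
#'
#' `P(t) = 1 + (p_ss - 1) * (1 - exp(-t/tau_ltp)) + a_ptp * exp(-t/tau_ptp)`
#' for `t >= 0` min after tetanus onset; 1 before.
#'
#' @param params A [sim_params()] object.
#' @param t_post_min Time since tetanus onset, min (vectorized).
#' @return Multiplicative potentiation factor(s).
#' @export
potentiation_factor <- function(params, t_post_min) {
  ifelse(t_post_min >= 0,
         1 + (params$p_ss - 1) * (1 - exp(-t_post_min / params$tau_ltp)) +
           params$a_ptp * exp(-t_post_min / params$tau_ptp),
         1)
}

# Unit-peak shapes (vectorized over t in ms, 0 before onset).
alpha_shape <- function(t, tau) {
  s <- t / tau
  ifelse(s > 0, s * exp(1 - s), 0)
}

dualexp_shape <- function(t, tau_rise, tau_decay) {
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  ifelse(t > 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak, 0)
}

# Deterministic per-sweep seed derivation (31-bit, order-independent mixing).
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) * 104729 + 11) %% m
  }
  as.integer(s)
}

#' Simulate one sweep
#'
#' Evaluates the generative model on the sample grid. With `noise_sd = 0`
#' and no population spikes the result equals the closed-form component sum
#' exactly; with a seed, repeated calls are bit-identical.
#'
#' @param params A [sim_params()] object.
#' @param intensity Stimulus current, uA (>= 0).
#' @param pulse_times Pulse times within the sweep, ms (absolute; default a
#'   single pulse at `params$stim_onset`).
#' @param t_acquired Sweep time within the experiment, min (drives drift).
#' @param t_post_tbs Time since tetanus onset, min; `NULL` (or negative) for
#'   no potentiation.
#' @param seed Integer seed for this sweep's noise and population spikes;
#'   `NULL` uses the current random stream.
#' @param sweep_index Ordinal stored on the sweep.
#' @return A [sweep_trace()].
#' @export
simulate_sweep <- function(params, intensity,
                           pulse_times = params$stim_onset,
                           t_acquired = 0, t_post_tbs = NULL,
                           seed = NULL, sweep_index = 1L) {
  if (intensity < 0) stop("'intensity' must be >= 0", call. = FALSE)
  n <- round(params$sweep_duration / params$sample_interval)
  tm <- (seq_len(n) - 1L) * params$sample_interval
  a_fv <- fv_amplitude(params, intensity)
  fac <- facilitation_factors(params, pulse_times)
  pot <- if (is.null(t_post_tbs)) 1 else potentiation_factor(params, t_post_tbs)

  v <- rep(params$drift_rate * t_acquired, n)
  for (k in seq_along(pulse_times)) {
    tk <- pulse_times[k]
    v <- v + params$artifact_amp * ifelse(tm >= tk, exp(-(tm - tk) / ARTIFACT_TAU), 0)
    if (a_fv > 0) {
      v <- v - a_fv * alpha_shape(tm - tk - params$fv_latency, params$fv_tau)
      v <- v - params$syn_gain * a_fv * fac[k] * pot *
        dualexp_shape(tm - tk - params$epsp_latency,
                      params$tau_rise, params$tau_decay)
    }
  }

  add_random <- function() {
    out <- numeric(n)
    if (params$popspike_rate > 0 && a_fv > 0) {
      t_peak <- params$tau_rise * params$tau_decay /
        (params$tau_decay - params$tau_rise) *
        log(params$tau_decay / params$tau_rise)
      for (k in seq_along(pulse_times)) {
        # spike incidence grows with recruitment: full rate at maximal
        # fiber volley, proportionally rarer near threshold
        n_sp <- stats::rpois(1L, params$popspike_rate * a_fv / params$fv_max)
        if (n_sp > 0L) {
          # spikes ride the falling phase of the fEPSP
          onset <- pulse_times[k] + params$epsp_latency + t_peak
          t_sp <- stats::runif(n_sp, onset + 1, onset + 25)
          for (ts in t_sp) {
            out <- out - params$popspike_amp * alpha_shape(tm - ts, POPSPIKE_TAU)
          }
        }
      }
    }
    if (params$noise_sd > 0) out <- out + stats::rnorm(n, 0, params$noise_sd)
    out
  }
  v <- v + if (is.null(seed)) add_random() else withr::with_seed(seed, add_random())

  sweep_trace(v, sample_interval = params$sample_interval,
              stimulus_times = pulse_times, stimulus_intensity = intensity,
              sweep_index = sweep_index, t_acquired = t_acquired)
}

# Theta-burst pulse times within one burst sweep (5 pulses at 100 Hz).
tbs_burst_pulses <- function(stim_onset) stim_onset + seq(0, 40, by = 10)

#' Simulate a full experiment
#'
#' Expands a [stimulus_protocol()] into a [recording()] of simulated sweeps.
#' Supported kinds:
#' \describe{
#'   \item{baseline}{One single-pulse sweep per entry of
#'     `protocol$intensities`, at the protocol's inter-sweep interval.}
#'   \item{io_ramp}{`sweeps_per_level` sweeps (default 6) at each intensity
#'     of the ramp.}
#'   \item{paired_pulse}{Sweeps with two pulses separated by `protocol$isi`.}
#'   \item{tbs}{One theta-burst episode as 10 burst sweeps, 5 pulses at
#'     100 Hz each, burst onsets 200 ms apart.}
#'   \item{ltp_experiment}{20 min of 0.1 Hz baseline (120 sweeps), one
#'     theta-burst episode, then follow-up sweeps with potentiation
#'     `P(t)` applied from tetanus onset.}
#' }
#'
#' @param params A [sim_params()] object; `params$seed` seeds the recording,
#'   and every sweep draws from a deterministically derived sub-stream, so
#'   identical seeds give identical recordings.
#' @param protocol A [stimulus_protocol()].
#' @param label,slice_id,animal_id Passed to [recording()].
#' @return A [recording()].
#' @export
simulate_experiment <- function(params, protocol, label = NA_character_,
                                slice_id = NA_character_,
                                animal_id = NA_character_) {
  isi_s <- protocol$inter_sweep_interval
  mk <- function(intensity, pulse_times, t_acq, t_post, idx) {
    simulate_sweep(params, intensity, pulse_times, t_acquired = t_acq,
                   t_post_tbs = t_post,
                   seed = derive_seed(params$seed, idx), sweep_index = idx)
  }
  sweeps <- switch(protocol$kind,
    baseline = {
      ints <- protocol$intensities
      lapply(seq_along(ints), function(i) {
        mk(ints[i], protocol$pulse_times + params$stim_onset,
           (i - 1L) * isi_s / 60, NULL, i)
      })
    },
    io_ramp = {
      per <- protocol$sweeps_per_level %||% 6L
      levels <- protocol$intensities
      idx <- 0L
      out <- vector("list", length(levels) * per)
      for (li in seq_along(levels)) {
        for (r in seq_len(per)) {
          idx <- idx + 1L
          out[[idx]] <- mk(levels[li], params$stim_onset,
                           (idx - 1L) * isi_s / 60, NULL, idx)
        }
      }
      out
    },
    paired_pulse = {
      nsw <- protocol$n_sweeps %||% 12L
      pt <- params$stim_onset + c(0, protocol$isi)
      lapply(seq_len(nsw), function(i) {
        mk(protocol$intensities[1L], pt, (i - 1L) * isi_s / 60, NULL, i)
      })
    },
    tbs = {
      lapply(seq_len(10L), function(b) {
        sw <- mk(protocol$intensities[1L], tbs_burst_pulses(params$stim_onset),
                 (b - 1L) * 0.2 / 60, NULL, b)
        sw$meta$phase <- "tbs"
        sw$meta$burst <- b
        sw
      })
    },
    ltp_experiment = {
      n_base <- round(protocol$baseline_min %||% 20 * 60 / isi_s)
      n_post <- round(protocol$followup_min %||% 60 * 60 / isi_s)
      intensity <- protocol$intensities[1L]
      t_tbs <- n_base * isi_s / 60
      base <- lapply(seq_len(n_base), function(i) {
        sw <- mk(intensity, params$stim_onset, (i - 1L) * isi_s / 60, NULL, i)
        sw$meta$phase <- "baseline"
        sw$meta$t_post_tbs <- (i - 1L) * isi_s / 60 - t_tbs
        sw
      })
      tet <- lapply(seq_len(10L), function(b) {
        idx <- n_base + b
        sw <- mk(intensity, tbs_burst_pulses(params$stim_onset),
                 t_tbs + (b - 1L) * 0.2 / 60, (b - 1L) * 0.2 / 60, idx)
        sw$meta$phase <- "tbs"
        sw$meta$burst <- b
        sw$meta$t_post_tbs <- (b - 1L) * 0.2 / 60
        sw
      })
      post <- lapply(seq_len(n_post), function(i) {
        idx <- n_base + 10L + i
        t_post <- i * isi_s / 60
        sw <- mk(intensity, params$stim_onset, t_tbs + t_post, t_post, idx)
        sw$meta$phase <- "followup"
        sw$meta$t_post_tbs <- t_post
        sw
      })
      c(base, tet, post)
    },
    stop("unsupported protocol kind: ", protocol$kind, call. = FALSE)
  )
  recording(sweeps, protocol = protocol, label = label,
            slice_id = slice_id, animal_id = animal_id)
}
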