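# Per-sweep measurements: stimulus detection, fiber-volley amplitude, fEPSP
# initial slope and amplitude, rectified depolarization AUC, and the
# modified Coastline Burst Index (mCBI).
#
# Sign convention: fEPSPs and fiber volleys are negative-going; amplitudes
# and slopes are reported as positive magnitudes relative to the
# pre-stimulus baseline, and the direction is fixed by that convention.

window_indices <- function(sweep, from, to) {
  tm <- sweep_times(sweep)
  which(tm >= from - 1e-9 & tm <= to + 1e-9)
}

#' Pre-stimulus baseline voltage
#'
#' Mean voltage over `[0, onset - gap]` ms, the quiet segment before the
#' stimulus artifact.
#'
#' @param sweep A [sweep_trace()].
#' @param onset Stimulus onset in ms (default: first annotation, else
#'   detected).
#' @param gap Guard interval before onset excluded from the baseline (ms).
#' @return Baseline voltage in mV.
#' @export
baseline_voltage <- function(sweep, onset = NULL, gap = 2) {
  if (is.null(onset)) onset <- detect_stimulus_onset(sweep)
  if (onset - gap <= 0) {
    stop("no pre-stimulus baseline segment before onset", call. = FALSE)
  }
  idx <- window_indices(sweep, 0, onset - gap)
  mean(sweep$samples[idx])
}

#' Locate the stimulus artifact
#'
#' Returns the annotated stimulus time when present; otherwise the time of
#' the first sample deviating from the pre-window mean by more than
#' `stim_z` pre-window standard deviations (resolution: one sample).
#'
#' @param sweep A [sweep_trace()].
#' @param stim_z Detection z-threshold over pre-stimulus noise.
#' @param pre_window Length of the initial segment used to estimate the
#'   noise level (ms).
#' @return Stimulus onset time in ms.
#' @export
detect_stimulus_onset <- function(sweep, stim_z = 6, pre_window = 5) {
  if (length(sweep$stimulus_times)) return(sweep$stimulus_times[1L])
  idx <- window_indices(sweep, 0, pre_window)
  m <- mean(sweep$samples[idx])
  s <- stats::sd(sweep$samples[idx])
  thr <- max(stim_z * s, 1e-3)  # 1 uV floor for noise-free traces
  hit <- which(abs(sweep$samples - m) > thr)
  hit <- hit[hit > max(idx)]
  if (!length(hit)) {
    stop("no stimulus artifact found and no annotation present", call. = FALSE)
  }
  (hit[1L] - 1L) * sweep$sample_interval
}

#' Fiber-volley amplitude
#'
#' Magnitude of the most negative deviation from the pre-stimulus baseline
#' within the fiber-volley window (default `onset + [0.5, 2.5]` ms), i.e.
#' the presynaptic compound action potential. Returns 0 when the trace does
#' not dip below baseline.
#'
#' @param sweep A [sweep_trace()].
#' @param window Absolute window in ms; default from `config` relative to
#'   `onset`.
#' @param onset Stimulus onset in ms (annotated/detected when `NULL`).
#' @param config An [analysis_config()].
#' @return Amplitude in mV (>= 0).
#' @export
measure_fiber_volley <- function(sweep, window = NULL, onset = NULL,
                                 config = analysis_config()) {
  if (is.null(onset)) onset <- detect_stimulus_onset(sweep)
  if (is.null(window)) window <- onset + config$windows$fv_window
  if (window[1L] < 0 || window[2L] > sweep_duration(sweep)) {
    stop("fiber-volley window lies outside the sweep", call. = FALSE)
  }
  b <- baseline_voltage(sweep, onset, config$windows$baseline_end_gap)
  idx <- window_indices(sweep, window[1L], window[2L])
  max(0, b - min(sweep$samples[idx]))
}

#' fEPSP initial slope (and peak amplitude)
#'
#' Finds the most negative deflection from baseline inside the search
#' window, then fits a least-squares line to the samples of the rising
#' (negative-going) phase whose deflection lies between `rise_fraction`
#' (default 20-80 %) of the peak. The slope magnitude in mV/ms is returned;
#' the fitted time window is attached as attribute `"fit_window"` and the
#' peak deflection as `"peak"`. A flat sweep (no deflection) yields 0.
#'
#' @param sweep A [sweep_trace()].
#' @param search_window Absolute window containing the fEPSP, ms; default
#'   `onset + config$windows$epsp_window`.
#' @param rise_fraction Lower/upper fractions of the peak bounding the fit
#'   region.
#' @param onset,config As in [measure_fiber_volley()].
#' @return Slope magnitude in mV/ms.
#' @export
measure_initial_slope <- function(sweep, search_window = NULL,
                                  rise_fraction = NULL, onset = NULL,
                                  config = analysis_config()) {
  if (is.null(onset)) onset <- detect_stimulus_onset(sweep)
  if (is.null(search_window)) search_window <- onset + config$windows$epsp_window
  if (is.null(rise_fraction)) rise_fraction <- config$windows$rise_fraction
  if (search_window[1L] < 0 || search_window[2L] > sweep_duration(sweep)) {
    stop("fEPSP search window lies outside the sweep", call. = FALSE)
  }
  b <- baseline_voltage(sweep, onset, config$windows$baseline_end_gap)
  pre <- window_indices(sweep, 0, onset - config$windows$baseline_end_gap)
  noise_floor <- 4 * stats::sd(sweep$samples[pre])
  idx <- window_indices(sweep, search_window[1L], search_window[2L])
  dev_raw <- b - sweep$samples[idx]       # positive downward
  peak_raw <- max(dev_raw)
  if (peak_raw <= max(noise_floor, 0)) {
    # no identifiable fEPSP above the pre-stimulus noise
    return(structure(0, peak = max(0, peak_raw),
                     fit_window = c(NA_real_, NA_real_)))
  }
  # selection trace: lightly smoothed when noise is appreciable relative to
  # the peak (the line is still fitted to the raw samples)
  devs <- b - sweep$samples
  if (noise_floor > 0.05 * peak_raw) {
    sm <- stats::filter(devs, rep(1 / 5, 5), sides = 2)
    devs <- ifelse(is.na(sm), devs, as.numeric(sm))
    # re-screen against the smoothed noise level: a marginal raw peak that
    # vanishes under smoothing is noise, not an fEPSP
    if (max(devs[idx]) <= 4 * stats::sd(devs[pre])) {
      return(structure(0, peak = max(0, peak_raw),
                       fit_window = c(NA_real_, NA_real_)))
    }
  }
  # the fEPSP peak is the FIRST prominent local maximum in the window;
  # later, larger deflections (population spikes riding the falling phase)
  # must not capture the fit
  dw <- devs[idx]
  n_w <- length(dw)
  half_w <- max(1L, as.integer(round(0.5 / sweep$sample_interval)))  # +/- 0.5 ms
  shoulders <- vapply(seq_len(n_w), function(i) {
    l <- max(1L, i - half_w)
    r <- min(n_w, i + half_w)
    c(max(dw[l:r]), min(dw[l], dw[r]))
  }, numeric(2))
  # prominent within its neighborhood, and broad: a synaptic peak keeps
  # most of its height 0.5 ms away, a population spike does not
  cand <- which(dw >= shoulders[1L, ] & shoulders[2L, ] >= 0.5 * dw &
                  dw >= 0.5 * max(dw) & dw > max(noise_floor, 0))
  if (!length(cand)) {
    # nothing fEPSP-shaped above the floor (e.g. an isolated narrow spike)
    return(structure(0, peak = max(0, peak_raw),
                     fit_window = c(NA_real_, NA_real_)))
  }
  ipk <- idx[cand[1L]]
  peak <- devs[ipk]
  lo <- rise_fraction[1L] * peak
  hi <- rise_fraction[2L] * peak
  i <- ipk
  while (i > idx[1L] && devs[i - 1L] > lo) i <- i - 1L
  rise_idx <- seq.int(i, ipk)
  fit_idx <- rise_idx[devs[rise_idx] >= lo - 1e-12 & devs[rise_idx] <= hi + 1e-12]
  # under noise the fractional band can be sparse; fall back to the whole
  # rising segment before declaring the sampling too coarse
  if (length(fit_idx) < 3L) fit_idx <- rise_idx[devs[rise_idx] <= hi + 1e-12]
  if (length(fit_idx) < 3L) {
    stop("fewer than 3 samples on the 20-80 % rising phase; ",
         "a denser sampling rate is required for the slope fit", call. = FALSE)
  }
  tt <- (fit_idx - 1L) * sweep$sample_interval
  vv <- sweep$samples[fit_idx]
  slope <- stats::cov(tt, vv) / stats::var(tt)
  structure(abs(slope), peak = max(0, b - sweep$samples[ipk]),
            fit_window = c(min(tt), max(tt)))
}

#' Rectified depolarization area under the curve
#'
#' Trapezoidal integral of `max(0, baseline - V(t))` over
#' `[start, start + duration]` ms: the rectified depolarizing (negative)
#' deviation from the pre-stimulus baseline, reported as a positive area.
#'
#' @param sweep A [sweep_trace()].
#' @param start Window start, ms.
#' @param duration Window length, ms (default 100).
#' @param onset,config As in [measure_fiber_volley()].
#' @return Area in mV.ms (>= 0).
#' @export
measure_auc <- function(sweep, start, duration = 100, onset = NULL,
                        config = analysis_config()) {
  if (start < 0 || start + duration > sweep_duration(sweep)) {
    stop("AUC window exceeds the sweep", call. = FALSE)
  }
  if (is.null(onset)) onset <- detect_stimulus_onset(sweep)
  b <- baseline_voltage(sweep, onset, config$windows$baseline_end_gap)
  idx <- window_indices(sweep, start, start + duration)
  y <- pmax(0, b - sweep$samples[idx])
  h <- sweep$sample_interval
  sum((y[-1L] + y[-length(y)]) / 2) * h
}

#' Modified Coastline Burst Index
#'
#' Sum of absolute consecutive-sample voltage differences over a
#' post-stimulus window (default \[25, 125\] ms), quantifying repetitive
#' spiking / hyperexcitability of the waveform. The number of samples used
#' is attached as attribute `"n_samples"`.
#'
#' @param sweep A [sweep_trace()].
#' @param window Absolute window in ms.
#' @return mCBI in mV (>= 0).
#' @export
#' @examples
#' sw <- sweep_trace(c(rep(0, 250), c(0, 1, 0, 1, 0), rep(0, 1000)))
#' compute_mcbi(sw, c(25, 25.4)) # 4 mV
compute_mcbi <- function(sweep, window = c(25, 125)) {
  if (window[1L] < 0 || window[2L] > sweep_duration(sweep)) {
    stop("mCBI window lies outside the sweep", call. = FALSE)
  }
  idx <- window_indices(sweep, window[1L], window[2L])
  if (length(idx) < 2L) {
    stop("mCBI window spans fewer than 2 samples", call. = FALSE)
  }
  structure(sum(abs(diff(sweep$samples[idx]))), n_samples = length(idx))
}

#' Normalize per-slice metric values to a reference mean
#'
#' Expresses group metrics relative to a control-group mean, so the control
#' group averages 1 when normalized by its own mean.
#'
#' @param values Numeric metric values.
#' @param reference_mean Positive reference (same units as `values`).
#' @return Dimensionless values `values / reference_mean`.
#' @export
normalize_metric <- function(values, reference_mean) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      !is.finite(reference_mean) || reference_mean <= 0) {
    stop("'reference_mean' must be a single positive number", call. = FALSE)
  }
  as.numeric(values) / reference_mean
}

#' Measure one sweep
#'
#' Convenience wrapper collecting the per-sweep measures into a one-row
#' data frame: stimulus time, fiber-volley amplitude, fEPSP initial slope
#' and amplitude, depolarization AUC (onset to onset + 100 ms) and mCBI.
#'
#' @param sweep A [sweep_trace()].
#' @param config An [analysis_config()].
#' @return A one-row `data.frame`.
#' @export
measure_sweep <- function(sweep, config = analysis_config()) {
  onset <- detect_stimulus_onset(sweep, stim_z = config$thresholds$stim_z)
  slope <- measure_initial_slope(sweep, onset = onset, config = config)
  auc_start <- onset
  auc_dur <- min(config$windows$auc_duration, sweep_duration(sweep) - onset)
  data.frame(
    sweep_index = sweep$sweep_index,
    t_acquired = sweep$t_acquired,
    intensity = sweep$stimulus_intensity,
    stim_time = onset,
    fv_amplitude = measure_fiber_volley(sweep, onset = onset, config = config),
    epsp_slope = as.numeric(slope),
    epsp_amplitude = attr(slope, "peak"),
    auc = measure_auc(sweep, auc_start, auc_dur, onset = onset, config = config),
    mcbi = as.numeric(compute_mcbi(sweep, config$windows$mcbi_window))
  )
}

#' Measure every sweep of a recording
#'
#' @param rec A [recording()].
#' @param config An [analysis_config()].
#' @return A `data.frame` with one [measure_sweep()] row per sweep.
#' @export
measure_recording <- function(rec, config = analysis_config()) {
  rows <- lapply(rec$sweeps, measure_sweep, config = config)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
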