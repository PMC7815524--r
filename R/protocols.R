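# Experiment-level analyses: protocol builders, input-output curves,
# paired-pulse ratio, baseline-stability screening, LTP magnitude, and
# tetanus depolarization.

#' Protocol builders
#'
#' Construct the standard stimulation protocols:
#' \describe{
#'   \item{`build_tbs()`}{One bout of theta-burst stimulation: five pulses
#'     at 100 Hz (10 ms spacing) repeated 10 times at 200 ms intervals —
#'     50 pulse times in all, relative to episode onset.}
#'   \item{`build_io_ramp()`}{Intensity ramp 0..`max_intensity` uA in
#'     `step` uA increments, `sweeps_per_level` sweeps per intensity.}
#'   \item{`build_paired_pulse()`}{Two pulses `isi` ms apart, repeated over
#'     `n_sweeps` sweeps at one intensity.}
#'   \item{`build_baseline()`}{Single-pulse sweeps at 0.1 Hz (default) for
#'     `duration_min` minutes.}
#'   \item{`build_ltp_protocol()`}{Baseline, one theta-burst bout, then
#'     follow-up at the baseline rate.}
#' }
#'
#' @return A [stimulus_protocol()].
#' @export
#' @examples
#' p <- build_tbs()
#' head(p$pulse_times, 5) # 0 10 20 30 40
build_tbs <- function() {
  bursts <- seq(0, 1800, by = 200)
  pulses <- as.vector(vapply(bursts, function(b) b + seq(0, 40, by = 10),
                             numeric(5)))
  stimulus_protocol("tbs", pulse_times = sort(pulses))
}

#' @rdname build_tbs
#' @param max_intensity,step Ramp ceiling and increment, uA.
#' @param sweeps_per_level Sweeps averaged per intensity (default 6).
#' @param inter_sweep_interval Seconds between sweeps (default 10, 0.1 Hz).
#' @export
build_io_ramp <- function(max_intensity = 320, step = 10,
                          sweeps_per_level = 6, inter_sweep_interval = 10) {
  p <- stimulus_protocol("io_ramp", intensities = seq(0, max_intensity, by = step),
                         inter_sweep_interval = inter_sweep_interval)
  p$sweeps_per_level <- sweeps_per_level
  p
}

#' @rdname build_tbs
#' @param intensity Stimulus current, uA.
#' @param isi Paired-pulse inter-stimulus interval, ms.
#' @param n_sweeps Number of paired-pulse sweeps.
#' @export
build_paired_pulse <- function(intensity, isi = 50, n_sweeps = 12,
                               inter_sweep_interval = 10) {
  p <- stimulus_protocol("paired_pulse", pulse_times = c(0, isi),
                         intensities = intensity, isi = isi,
                         inter_sweep_interval = inter_sweep_interval)
  p$n_sweeps <- n_sweeps
  p
}

#' @rdname build_tbs
#' @param duration_min Baseline length, min.
#' @export
build_baseline <- function(intensity, duration_min = 20,
                           inter_sweep_interval = 10) {
  n <- round(duration_min * 60 / inter_sweep_interval)
  stimulus_protocol("baseline", intensities = rep(intensity, n),
                    inter_sweep_interval = inter_sweep_interval)
}

#' @rdname build_tbs
#' @param baseline_min,followup_min Baseline and follow-up durations, min.
#' @export
build_ltp_protocol <- function(intensity, baseline_min = 20, followup_min = 60,
                               inter_sweep_interval = 10) {
  p <- stimulus_protocol("ltp_experiment", intensities = intensity,
                         inter_sweep_interval = inter_sweep_interval)
  p$baseline_min <- baseline_min
  p$followup_min <- followup_min
  p$tbs <- build_tbs()
  p
}

#' Input-output curve
#'
#' Averages the fEPSP initial slope and fiber-volley amplitude of the
#' sweeps recorded at each stimulus intensity. Intensities represented by
#' fewer sweeps than `expected_sweeps` are flagged; intensities with no
#' sweeps are omitted with a warning.
#'
#' @param rec An `io_ramp` [recording()].
#' @param config An [analysis_config()].
#' @param expected_sweeps Sweeps expected per intensity (default 6).
#' @return A `fieldlab_iocurve`: list with `curve` (data frame of
#'   `intensity`, `mean_slope`, `mean_fv`, `n_sweeps`, `underpowered`) and
#'   `per_sweep` (all per-sweep measures).
#' @export
analyze_io <- function(rec, config = analysis_config(), expected_sweeps = 6L) {
  meas <- measure_recording(rec, config)
  levels <- sort(unique(meas$intensity))
  curve <- do.call(rbind, lapply(levels, function(I) {
    m <- meas[meas$intensity == I, , drop = FALSE]
    data.frame(intensity = I,
               mean_slope = mean(m$epsp_slope),
               mean_fv = mean(m$fv_amplitude),
               n_sweeps = nrow(m),
               underpowered = nrow(m) < expected_sweeps)
  }))
  if (any(curve$underpowered)) {
    warning(sprintf("%d intensity level(s) have fewer than %d sweeps",
                    sum(curve$underpowered), expected_sweeps), call. = FALSE)
  }
  structure(list(curve = curve, per_sweep = meas), class = "fieldlab_iocurve")
}

#' @export
print.fieldlab_iocurve <- function(x, ...) {
  cat(sprintf("<fieldlab_iocurve> %d intensities, max mean slope %.3g mV/ms, max mean FV %.3g mV\n",
              nrow(x$curve), max(x$curve$mean_slope), max(x$curve$mean_fv)))
  invisible(x)
}

#' Intensity eliciting about half the maximal response
#'
#' Operationalizes "stimulus strength set to elicit ~50 % of the maximal
#' response": the ramp intensity whose mean slope is nearest 50 % of the
#' input-output maximum.
#'
#' @param io A `fieldlab_iocurve` from [analyze_io()].
#' @return Intensity in uA.
#' @export
halfmax_intensity <- function(io) {
  cv <- io$curve
  target <- 0.5 * max(cv$mean_slope)
  cv$intensity[which.min(abs(cv$mean_slope - target))]
}

# Mono-exponential fit to the decaying tail of the first response,
# extrapolated past the second pulse so the second slope can be measured
# on a first-response-free trace. Returns the corrected sweep.
subtract_first_tail <- function(sweep, onset1, onset2, peak_frac_warn = 0.05,
                                config = analysis_config()) {
  b <- baseline_voltage(sweep, onset1, config$windows$baseline_end_gap)
  s1 <- measure_initial_slope(
    sweep, search_window = c(onset1 + config$windows$epsp_window[1L], onset2),
    onset = onset1, config = config)
  peak1 <- attr(s1, "peak")
  tm <- sweep_times(sweep)
  # decay segment: well past the first peak, up to just before the second pulse
  fit_idx <- window_indices(sweep, onset1 + 12, onset2 - 1)
  dev <- b - sweep$samples[fit_idx]
  keep <- dev > 0
  tail_mag <- if (length(dev)) mean(pmax(dev, 0)) else 0
  corrected <- sweep
  if (sum(keep) >= 3L) {
    tt <- tm[fit_idx][keep]
    ld <- log(dev[keep])
    beta <- stats::cov(tt, ld) / stats::var(tt)
    alpha <- mean(ld) - beta * mean(tt)
    if (is.finite(alpha) && is.finite(beta) && beta < 0) {
      after <- tm >= onset2
      corrected$samples[after] <- sweep$samples[after] + exp(alpha + beta * tm[after])
      return(corrected)
    }
  }
  if (tail_mag > peak_frac_warn * peak1) {
    stop(sprintf("sweep %d: first-response tail fit failed with overlapping responses",
                 sweep$sweep_index), call. = FALSE)
  }
  corrected  # tail negligible; nothing to subtract
}

#' Paired-pulse ratio
#'
#' For each paired-pulse sweep, measures the initial slope of the first
#' fEPSP, subtracts a mono-exponential extrapolation of its decaying tail,
#' then measures the second slope. The headline ratio is formed from the
#' across-sweep mean slopes, `ppr = mean(slope2) / mean(slope1)`, which is
#' unbiased under measurement noise; per-sweep ratios are retained.
#'
#' @param rec A `paired_pulse` [recording()] with two stimulus annotations
#'   per sweep.
#' @param config An [analysis_config()].
#' @return A `fieldlab_ppr`: list with `slope1`, `slope2`, `ppr` (means),
#'   `isi`, and `per_sweep`.
#' @export
analyze_ppr <- function(rec, config = analysis_config()) {
  rows <- lapply(rec$sweeps, function(sw) {
    if (length(sw$stimulus_times) < 2L) {
      stop(sprintf("sweep %d has no second pulse", sw$sweep_index), call. = FALSE)
    }
    o1 <- sw$stimulus_times[1L]
    o2 <- sw$stimulus_times[2L]
    w <- config$windows$epsp_window
    s1 <- measure_initial_slope(sw, search_window = c(o1 + w[1L], min(o1 + w[2L], o2)),
                                onset = o1, config = config)
    corrected <- subtract_first_tail(sw, o1, o2, config = config)
    s2 <- measure_initial_slope(corrected,
                                search_window = c(o2 + w[1L],
                                                  min(o2 + w[2L], sweep_duration(sw))),
                                onset = o1, config = config)
    if (s1 <= 0) stop(sprintf("sweep %d: no first response", sw$sweep_index),
                      call. = FALSE)
    data.frame(sweep_index = sw$sweep_index, slope1 = as.numeric(s1),
               slope2 = as.numeric(s2), ppr = as.numeric(s2) / as.numeric(s1))
  })
  per_sweep <- do.call(rbind, rows)
  structure(list(slope1 = mean(per_sweep$slope1),
                 slope2 = mean(per_sweep$slope2),
                 ppr = mean(per_sweep$slope2) / mean(per_sweep$slope1),
                 isi = if (!is.null(rec$protocol)) rec$protocol$isi else
                   diff(rec$sweeps[[1L]]$stimulus_times[1:2]),
                 per_sweep = per_sweep),
            class = "fieldlab_ppr")
}

#' @export
print.fieldlab_ppr <- function(x, ...) {
  cat(sprintf("<fieldlab_ppr> PPR %.3f at %g ms ISI over %d sweep(s)\n",
              x$ppr, x$isi, nrow(x$per_sweep)))
  invisible(x)
}

#' Baseline-stability screening
#'
#' Computes the baseline variance statistic used for inclusion: the
#' coefficient of variation (percent) of 1-min binned mean slopes about the
#' overall baseline mean. Experiments are included when the statistic does
#' not exceed `limit` (default 8 %).
#'
#' @param slopes Per-sweep baseline fEPSP slopes (mV/ms).
#' @param times_min Acquisition time of each sweep, min.
#' @param limit Inclusion limit, percent.
#' @return List with `included` (logical), `variance_pct`, and `n_bins`.
#' @export
check_baseline_stability <- function(slopes, times_min, limit = 8) {
  if (length(slopes) != length(times_min)) {
    stop("'slopes' and 'times_min' must have equal length", call. = FALSE)
  }
  if (length(slopes) < 10L) {
    stop("at least 10 baseline sweeps are required", call. = FALSE)
  }
  bins <- floor(times_min - min(times_min))
  if (max(times_min) - min(times_min) < 1) {
    stop("baseline spans less than one 1-min bin", call. = FALSE)
  }
  bin_means <- tapply(slopes, bins, mean)
  overall <- mean(slopes)
  if (overall <= 0) stop("baseline mean slope must be positive", call. = FALSE)
  variance_pct <- 100 * stats::sd(bin_means) / overall
  list(included = variance_pct <= limit, variance_pct = variance_pct,
       n_bins = length(bin_means))
}

#' LTP time course and magnitude
#'
#' Normalizes every fEPSP slope to the mean of the pre-tetanus baseline
#' (= 100 %), bins the time course per minute relative to tetanus onset
#' (baseline at negative times), and reports the LTP magnitude as the mean
#' normalized slope over the analysis window (default 44-59 min
#' post-tetanus). The baseline fiber-volley mean is retained for the
#' cross-group stimulation-strength control, and the baseline-stability
#' rule decides inclusion.
#'
#' @param rec An `ltp_experiment` [recording()] from [simulate_experiment()]
#'   or with equivalent per-sweep `meta$phase` / `meta$t_post_tbs`
#'   annotations.
#' @param config An [analysis_config()].
#' @return A `fieldlab_ltp`: list with `timecourse` (minute-binned data
#'   frame), `baseline_mean_slope`, `ltp_magnitude` (percent of baseline),
#'   `analysis_window`, `baseline_fv`, `included`, `variance_pct`, and
#'   `per_sweep`.
#' @export
analyze_ltp <- function(rec, config = analysis_config()) {
  phase <- vapply(rec$sweeps, function(s) s$meta$phase %||% NA_character_,
                  character(1))
  if (anyNA(phase)) stop("LTP analysis needs per-sweep phase annotations",
                         call. = FALSE)
  t_rel <- vapply(rec$sweeps, function(s) s$meta$t_post_tbs %||% NA_real_,
                  numeric(1))
  window <- config$windows$ltp_window
  if (max(t_rel, na.rm = TRUE) < window[2L]) {
    stop("analysis window extends beyond the end of the recording", call. = FALSE)
  }
  single <- phase %in% c("baseline", "followup")
  meas <- do.call(rbind, lapply(rec$sweeps[single], measure_sweep, config = config))
  meas$phase <- phase[single]
  meas$t_rel <- t_rel[single]
  base <- meas[meas$phase == "baseline", , drop = FALSE]
  baseline_mean <- mean(base$epsp_slope)
  if (baseline_mean <= 0) stop("degenerate baseline: mean slope is not positive",
                               call. = FALSE)
  meas$norm_slope <- 100 * meas$epsp_slope / baseline_mean
  stab <- check_baseline_stability(base$epsp_slope, base$t_acquired,
                                   limit = config$thresholds$baseline_variance_limit)
  bins <- floor(meas$t_rel)
  tc <- data.frame(t_min = sort(unique(bins)))
  tc$normalized_slope <- as.numeric(
    tapply(meas$norm_slope, bins, mean)[as.character(tc$t_min)])
  in_win <- meas$t_rel >= window[1L] & meas$t_rel <= window[2L]
  structure(list(
    timecourse = tc,
    baseline_mean_slope = baseline_mean,
    ltp_magnitude = mean(meas$norm_slope[in_win]),
    analysis_window = window,
    baseline_fv = mean(base$fv_amplitude),
    included = stab$included,
    inclusion_reason = sprintf("baseline variance %.2f%% (limit %g%%)",
                               stab$variance_pct,
                               config$thresholds$baseline_variance_limit),
    variance_pct = stab$variance_pct,
    per_sweep = meas
  ), class = "fieldlab_ltp")
}

#' @export
print.fieldlab_ltp <- function(x, ...) {
  cat(sprintf("<fieldlab_ltp> %.1f%% of baseline over [%g, %g] min; %s\n",
              x$ltp_magnitude, x$analysis_window[1L], x$analysis_window[2L],
              if (x$included) "included" else paste("EXCLUDED:", x$inclusion_reason)))
  invisible(x)
}

#' Postsynaptic depolarization during the tetanus
#'
#' Integrates the rectified depolarization over `[onset, onset + 100]` ms
#' for each theta burst and averages across the 10 bursts. Burst onsets are
#' taken from the stimulus annotations: pulses more than 100 ms after their
#' predecessor (or the first pulse of a sweep) start a new burst.
#'
#' @param tbs_sweeps A list of [sweep_trace()] objects (or a [recording()])
#'   covering the tetanus.
#' @param config An [analysis_config()].
#' @param n_bursts Bursts expected (default 10).
#' @return A `fieldlab_auc`: list with `per_burst_auc` and `mean_auc`
#'   (mV.ms).
#' @export
tetanus_depolarization <- function(tbs_sweeps, config = analysis_config(),
                                   n_bursts = 10L) {
  if (inherits(tbs_sweeps, "fieldlab_recording")) tbs_sweeps <- tbs_sweeps$sweeps
  onsets <- list()
  for (sw in tbs_sweeps) {
    st <- sw$stimulus_times
    if (!length(st)) next
    starts <- st[c(TRUE, diff(st) > 100)]
    for (o in starts) onsets[[length(onsets) + 1L]] <- list(sweep = sw, onset = o)
  }
  if (length(onsets) != n_bursts) {
    found <- length(onsets)
    stop(sprintf("expected %d tetanus bursts, found %d (missing burst indices: %s)",
                 n_bursts, found,
                 if (found < n_bursts)
                   paste(seq.int(found + 1L, n_bursts), collapse = ", ")
                 else "none"),
         call. = FALSE)
  }
  dur <- config$windows$auc_duration
  per <- vapply(onsets, function(b) {
    measure_auc(b$sweep, start = b$onset, duration = dur,
                onset = b$onset, config = config)
  }, numeric(1))
  structure(list(per_burst_auc = per, mean_auc = mean(per)),
            class = "fieldlab_auc")
}

#' @export
print.fieldlab_auc <- function(x, ...) {
  cat(sprintf("<fieldlab_auc> mean %.3g mV.ms over %d burst(s)\n",
              x$mean_auc, length(x$per_burst_auc)))
  invisible(x)
}
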