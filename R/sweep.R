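# Core domain objects: Sweep, Recording, StimulusProtocol.
# Canonical units throughout the package: voltage mV, time within a sweep ms,
# stimulus current uA, experiment time min. All readers convert on ingest.

#' Construct a single digitized sweep
#'
#' A `fieldlab_sweep` holds one extracellular voltage trace together with its
#' time base and stimulus annotations. Time within a sweep is 0-based at the
#' first sample; stimulus times are absolute within the sweep.
#'
#' @param samples Numeric vector of voltages in mV, one per sample.
#' @param sample_interval Sampling interval in ms per sample (default 0.1 ms,
#'   i.e. 10 kHz).
#' @param stimulus_times Strictly increasing stimulus times in ms, all inside
#'   `[0, length(samples) * sample_interval)`.
#' @param stimulus_intensity Stimulus current in uA.
#' @param sweep_index Ordinal position of the sweep within its recording.
#' @param t_acquired Time offset of the sweep within the experiment, in min.
#' @param meta Free-form named list of acquisition metadata.
#'
#' @return An object of class `fieldlab_sweep`.
#' @export
#' @examples
#' sw <- sweep_trace(rep(0, 2000))
#' sweep_duration(sw) # 200 ms
sweep_trace <- function(samples,
                        sample_interval = 0.1,
                        stimulus_times = numeric(),
                        stimulus_intensity = NA_real_,
                        sweep_index = 1L,
                        t_acquired = 0,
                        meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a sweep needs at least 2 samples", call. = FALSE)
  }
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    stop("'sample_interval' must be a single positive number (ms)", call. = FALSE)
  }
  stimulus_times <- as.numeric(stimulus_times)
  dur <- length(samples) * sample_interval
  if (length(stimulus_times)) {
    if (any(diff(stimulus_times) <= 0)) {
      stop("'stimulus_times' must be strictly increasing", call. = FALSE)
    }
    if (any(stimulus_times < 0 | stimulus_times >= dur)) {
      stop("'stimulus_times' must lie within [0, sweep duration)", call. = FALSE)
    }
  }
  structure(
    list(
      samples = samples,
      sample_interval = sample_interval,
      stimulus_times = stimulus_times,
      stimulus_intensity = as.numeric(stimulus_intensity),
      sweep_index = as.integer(sweep_index),
      t_acquired = as.numeric(t_acquired),
      meta = meta
    ),
    class = "fieldlab_sweep"
  )
}

#' Sweep time axis and duration
#'
#' @param sweep A [sweep_trace()] object.
#' @return `sweep_times()` returns the sample times in ms (0-based);
#'   `sweep_duration()` the total duration in ms.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1L) * sweep$sample_interval
}

#' @rdname sweep_times
#' @export
sweep_duration <- function(sweep) {
  length(sweep$samples) * sweep$sample_interval
}

#' @export
print.fieldlab_sweep <- function(x, ...) {
  cat(sprintf(
    "<fieldlab_sweep> %d samples @ %.4g ms (%.4g ms), %d stimulus pulse(s), %.4g uA, t = %.3g min\n",
    length(x$samples), x$sample_interval, sweep_duration(x),
    length(x$stimulus_times), x$stimulus_intensity, x$t_acquired
  ))
  invisible(x)
}

#' Describe a stimulation protocol
#'
#' A declarative description of an experiment as pulse times and per-sweep
#' intensities: a low-frequency baseline train, an input-output intensity
#' ramp, a paired-pulse probe, a theta-burst episode, or a full LTP
#' experiment (baseline, one theta-burst bout, follow-up).
#'
#' @param kind One of `"baseline"`, `"io_ramp"`, `"paired_pulse"`, `"tbs"`,
#'   `"ltp_experiment"`.
#' @param pulse_times Pulse times in ms, relative to stimulus onset within a
#'   sweep (single pulse at 0 by default).
#' @param intensities Stimulus current(s) in uA; for `io_ramp`, the ramp of
#'   per-intensity levels.
#' @param inter_sweep_interval Time between successive sweeps, in s
#'   (default 10 s, i.e. 0.1 Hz).
#' @param pulse_width Stimulus pulse width in us (default 200, metadata only;
#'   the simulator does not resolve the pulse shape).
#' @param isi Paired-pulse inter-stimulus interval in ms (default 50).
#'
#' @return An object of class `fieldlab_protocol`.
#' @export
stimulus_protocol <- function(kind,
                              pulse_times = 0,
                              intensities = numeric(),
                              inter_sweep_interval = 10,
                              pulse_width = 200,
                              isi = 50) {
  kind <- match.arg(kind,
                    c("baseline", "io_ramp", "paired_pulse", "tbs", "ltp_experiment"))
  if (kind == "io_ramp" && length(intensities) >= 3L) {
    steps <- diff(intensities)
    if (any(abs(steps - steps[1L]) > 1e-9)) {
      stop("'io_ramp' intensities must form an arithmetic ramp", call. = FALSE)
    }
  }
  structure(
    list(
      kind = kind,
      pulse_times = as.numeric(pulse_times),
      intensities = as.numeric(intensities),
      inter_sweep_interval = inter_sweep_interval,
      pulse_width = pulse_width,
      isi = isi
    ),
    class = "fieldlab_protocol"
  )
}

#' @export
print.fieldlab_protocol <- function(x, ...) {
  cat(sprintf("<fieldlab_protocol> kind=%s, %d pulse(s)/sweep, %d intensity level(s)\n",
              x$kind, length(x$pulse_times), length(x$intensities)))
  invisible(x)
}

#' Bundle sweeps into a recording
#'
#' @param sweeps List of [sweep_trace()] objects sharing one sample interval,
#'   with non-decreasing `t_acquired`.
#' @param protocol The [stimulus_protocol()] that generated the sweeps.
#' @param label Condition tag, e.g. `"air"` or `"hyperoxia"`.
#' @param slice_id,animal_id Identifiers carried through to results tables.
#'
#' @return An object of class `fieldlab_recording`.
#' @export
recording <- function(sweeps, protocol = NULL, label = NA_character_,
                      slice_id = NA_character_, animal_id = NA_character_) {
  if (!length(sweeps)) stop("a recording needs at least one sweep", call. = FALSE)
  if (!all(vapply(sweeps, inherits, logical(1), "fieldlab_sweep"))) {
    stop("'sweeps' must be a list of fieldlab_sweep objects", call. = FALSE)
  }
  si <- vapply(sweeps, `[[`, numeric(1), "sample_interval")
  if (any(abs(si - si[1L]) > 1e-12)) {
    stop("all sweeps in a recording must share one sample_interval", call. = FALSE)
  }
  tacq <- vapply(sweeps, `[[`, numeric(1), "t_acquired")
  if (any(diff(tacq) < 0)) {
    stop("sweep 't_acquired' must be non-decreasing", call. = FALSE)
  }
  structure(
    list(sweeps = sweeps, protocol = protocol, label = label,
         slice_id = slice_id, animal_id = animal_id),
    class = "fieldlab_recording"
  )
}

#' @export
print.fieldlab_recording <- function(x, ...) {
  cat(sprintf("<fieldlab_recording> %d sweep(s), label=%s, protocol=%s\n",
              length(x$sweeps), x$label,
              if (is.null(x$protocol)) "<none>" else x$protocol$kind))
  invisible(x)
}

#' @export
length.fieldlab_recording <- function(x) length(x$sweeps)
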