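# Analysis configuration: measurement windows, inclusion thresholds,
# simulation layout and statistics options, with strict key validation.

config_defaults <- function() {
  list(
    windows = list(
      # ms relative to stimulus onset
      fv_window = c(0.5, 2.5),
      epsp_window = c(2.5, 30),
      # ms absolute within the sweep (stimulus onset defaults to 20 ms,
      # so 25 ms is 5 ms after the artifact)
      mcbi_window = c(25, 125),
      auc_duration = 100,
      # min post-tetanus over which LTP magnitude is averaged
      ltp_window = c(44, 59),
      # fraction of the fEPSP rising phase used for the initial-slope fit
      rise_fraction = c(0.2, 0.8),
      # baseline voltage = mean of [0, onset - baseline_end_gap] ms
      baseline_end_gap = 2
    ),
    thresholds = list(
      baseline_variance_limit = 8,  # percent CV of 1-min binned slopes
      stim_z = 6                    # z-threshold for artifact detection
    ),
    simulation = list(
      isi = 50,                     # paired-pulse inter-stimulus interval, ms
      stim_onset = 20,              # ms
      sweep_duration = 200,         # ms
      inter_sweep_interval = 10,    # s (0.1 Hz)
      baseline_min = 20,            # min of baseline before tetanus
      followup_min = 60,            # min of follow-up after tetanus
      sweeps_per_intensity = 6,
      io_max_intensity = 320,       # uA
      io_step = 10,                 # uA
      ppr_sweeps = 12
    ),
    stats = list(
      alpha = 0.05,
      grubbs_screen = TRUE
    )
  )
}

validate_config <- function(cfg) {
  w <- cfg$windows
  th <- cfg$thresholds
  stopifnot_cfg <- function(ok, msg) {
    if (!ok) stop("invalid configuration: ", msg, call. = FALSE)
  }
  for (nm in c("fv_window", "epsp_window", "mcbi_window", "ltp_window",
               "rise_fraction")) {
    v <- w[[nm]]
    stopifnot_cfg(is.numeric(v) && length(v) == 2L && v[1L] < v[2L],
                  sprintf("'%s' must be an increasing interval", nm))
  }
  stopifnot_cfg(all(w$rise_fraction > 0) && all(w$rise_fraction < 1),
                "'rise_fraction' bounds must lie in (0, 1)")
  stopifnot_cfg(is.numeric(w$auc_duration) && w$auc_duration > 0,
                "'auc_duration' must be > 0")
  stopifnot_cfg(is.numeric(th$baseline_variance_limit) &&
                  th$baseline_variance_limit > 0,
                "'baseline_variance_limit' must be > 0 (percent)")
  stopifnot_cfg(is.numeric(th$stim_z) && th$stim_z > 0, "'stim_z' must be > 0")
  stopifnot_cfg(cfg$stats$alpha > 0 && cfg$stats$alpha < 1,
                "'alpha' must lie in (0, 1)")
  stopifnot_cfg(is.numeric(cfg$simulation$isi) && cfg$simulation$isi > 0,
                "'isi' must be > 0 (ms)")
  invisible(cfg)
}

merge_config_section <- function(defaults, user, section) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s) in [%s]: %s",
                 section, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(user)) defaults[[nm]] <- unlist(user[[nm]], use.names = FALSE)
  defaults
}

#' Build or load an analysis configuration
#'
#' `analysis_config()` assembles a configuration from defaults plus named
#' overrides; `load_config()` reads one from a YAML (or JSON) file with
#' sections `windows`, `thresholds`, `simulation` and `stats`. Unknown
#' sections or keys are rejected, and threshold values are range-checked.
#' An empty file yields all defaults, among them a baseline variance limit
#' of 8 %, a 50 ms paired-pulse interval, and a coastline window of
#' \[25, 125\] ms.
#'
#' @param windows,thresholds,simulation,stats Named lists of overrides for
#'   the corresponding section.
#' @return An object of class `fieldlab_config`: a named list with the four
#'   sections.
#' @export
#' @examples
#' cfg <- analysis_config(windows = list(mcbi_window = c(25, 70)))
#' cfg$windows$mcbi_window
analysis_config <- function(windows = list(), thresholds = list(),
                            simulation = list(), stats = list()) {
  def <- config_defaults()
  cfg <- list(
    windows = merge_config_section(def$windows, windows, "windows"),
    thresholds = merge_config_section(def$thresholds, thresholds, "thresholds"),
    simulation = merge_config_section(def$simulation, simulation, "simulation"),
    stats = merge_config_section(def$stats, stats, "stats")
  )
  class(cfg) <- "fieldlab_config"
  validate_config(cfg)
}

#' @rdname analysis_config
#' @param path Path to a YAML or JSON configuration file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration file must contain a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), c("windows", "thresholds", "simulation", "stats"))
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  analysis_config(
    windows = if (is.null(raw$windows)) list() else raw$windows,
    thresholds = if (is.null(raw$thresholds)) list() else raw$thresholds,
    simulation = if (is.null(raw$simulation)) list() else raw$simulation,
    stats = if (is.null(raw$stats)) list() else raw$stats
  )
}

#' @export
print.fieldlab_config <- function(x, ...) {
  cat("<fieldlab_config>\n")
  for (sec in names(x)) {
    cat(sprintf("  [%s] %s\n", sec,
                paste(sprintf("%s=%s", names(x[[sec]]),
                              vapply(x[[sec]], function(v) paste(v, collapse = ":"),
                                     character(1))),
                      collapse = ", ")))
  }
  invisible(x)
}
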