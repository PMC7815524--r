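# Sweep-table readers and writers.
#
# Two plain-text dialects share one JSON sidecar (<name>.meta.json) carrying
# stimulus annotations and labels:
#   csv - header `time_ms,sweep_0001,...`, one row per sample;
#   atf - Axon Text File: line 1 `ATF<TAB>1.0`, line 2
#         `<nHeaderRecords><TAB><nColumns>`, optional quoted header records,
#         a column-title line, then tab-delimited rows time (ms) + sweeps (mV).

sidecar_path <- function(path) {
  sub("\\.[^./\\\\]+$", "", path) |> paste0(".meta.json")
}

read_sidecar <- function(path, n_sweeps) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    return(list(stimulus_times = rep(list(numeric()), n_sweeps),
                intensities = rep(NA_real_, n_sweeps),
                t_acquired = rep(0, n_sweeps),
                phase = rep(NA_character_, n_sweeps),
                t_post_tbs = rep(NA_real_, n_sweeps),
                inter_sweep_interval = 10,
                label = NA_character_, slice_id = NA_character_,
                animal_id = NA_character_, protocol = NULL))
  }
  meta <- jsonlite::read_json(sp, simplifyVector = FALSE)
  st <- meta$stimulus_times
  if (is.null(st)) st <- rep(list(numeric()), n_sweeps)
  st <- lapply(st, function(x) as.numeric(unlist(x)))
  list(
    stimulus_times = st,
    intensities = if (is.null(meta$intensities)) rep(NA_real_, n_sweeps)
                  else as.numeric(unlist(meta$intensities)),
    t_acquired = if (is.null(meta$t_acquired)) rep(0, n_sweeps)
                 else as.numeric(unlist(meta$t_acquired)),
    phase = if (is.null(meta$phase)) rep(NA_character_, n_sweeps)
            else vapply(meta$phase, function(x)
              if (is.null(x)) NA_character_ else as.character(x), character(1),
              USE.NAMES = FALSE),
    t_post_tbs = if (is.null(meta$t_post_tbs)) rep(NA_real_, n_sweeps)
                 else vapply(meta$t_post_tbs, function(x)
                   if (is.null(x)) NA_real_ else as.numeric(x), numeric(1),
                   USE.NAMES = FALSE),
    inter_sweep_interval = meta$inter_sweep_interval %||% 10,
    label = meta$label %||% NA_character_,
    slice_id = meta$slice_id %||% NA_character_,
    animal_id = meta$animal_id %||% NA_character_,
    protocol = meta$protocol
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_time_column <- function(tm) {
  if (length(tm) < 2L) stop("sweep table has fewer than 2 samples", call. = FALSE)
  d <- diff(tm)
  if (any(d <= 0)) stop("non-monotonic time column in sweep table", call. = FALSE)
  if (max(d) - min(d) > 1e-6 * mean(d)) {
    stop("time column is not uniformly sampled", call. = FALSE)
  }
  mean(d)
}

#' Read a sweep table from disk
#'
#' Parses a CSV or ATF sweep table (plus its JSON sidecar, when present)
#' into a [recording()]. Voltages are interpreted as mV and times as ms.
#' One sweep is produced per data column; sweeps are never silently dropped.
#'
#' @param path Path to the sweep-table file.
#' @param dialect `"csv"` or `"atf"`; defaults to the file extension.
#' @return A [recording()].
#' @export
read_sweep_table <- function(path, dialect = c("csv", "atf")) {
  if (missing(dialect)) {
    dialect <- if (grepl("\\.atf$", path, ignore.case = TRUE)) "atf" else "csv"
  }
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE)
    if (ncol(tab) < 2L || names(tab)[1L] != "time_ms") {
      stop("malformed CSV header (line 1): expected 'time_ms,sweep_0001,...'",
           call. = FALSE)
    }
  } else {
    lines <- readLines(path, n = 2L)
    if (length(lines) < 2L || !grepl("^ATF\t", lines[1L])) {
      stop("malformed ATF header (line 1): expected 'ATF\\t1.0'", call. = FALSE)
    }
    hdr <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    n_opt <- suppressWarnings(as.integer(hdr[1L]))
    n_col <- suppressWarnings(as.integer(hdr[2L]))
    if (length(hdr) < 2L || is.na(n_opt) || is.na(n_col)) {
      stop("malformed ATF header (line 2): expected '<nHeaderRecords>\\t<nColumns>'",
           call. = FALSE)
    }
    tab <- utils::read.delim(path, skip = 2L + n_opt, check.names = FALSE)
    if (ncol(tab) != n_col) {
      stop(sprintf("ATF column count mismatch: header declares %d, found %d",
                   n_col, ncol(tab)), call. = FALSE)
    }
  }
  tm <- as.numeric(tab[[1L]])
  si <- check_time_column(tm)
  n_sweeps <- ncol(tab) - 1L
  meta <- read_sidecar(path, n_sweeps)
  sweeps <- lapply(seq_len(n_sweeps), function(i) {
    sw_meta <- list()
    if (!is.na(meta$phase[i] %||% NA)) sw_meta$phase <- meta$phase[i]
    if (!is.na(meta$t_post_tbs[i] %||% NA)) sw_meta$t_post_tbs <- meta$t_post_tbs[i]
    sweep_trace(
      samples = as.numeric(tab[[i + 1L]]),
      sample_interval = si,
      stimulus_times = if (i <= length(meta$stimulus_times))
        meta$stimulus_times[[i]] else numeric(),
      stimulus_intensity = meta$intensities[i],
      sweep_index = i,
      t_acquired = meta$t_acquired[i],
      meta = sw_meta
    )
  })
  proto <- NULL
  if (!is.null(meta$protocol) && !is.null(meta$protocol$kind)) {
    proto <- stimulus_protocol(
      kind = meta$protocol$kind,
      pulse_times = meta$protocol$pulse_times %||% 0,
      intensities = meta$protocol$intensities %||% numeric(),
      inter_sweep_interval = meta$inter_sweep_interval,
      isi = meta$protocol$isi %||% 50
    )
  }
  recording(sweeps, protocol = proto, label = meta$label,
            slice_id = meta$slice_id, animal_id = meta$animal_id)
}

#' Write a recording as a sweep table
#'
#' Writes a [recording()] as a CSV or ATF sweep table plus a JSON sidecar
#' holding stimulus times, intensities, acquisition times and labels.
#' Voltages are written with 8 significant digits so a round trip through
#' [read_sweep_table()] is value-identical well beyond 6 significant digits.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param dialect `"csv"` or `"atf"`.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(rec, path, dialect = c("csv", "atf")) {
  if (!inherits(rec, "fieldlab_recording") || !length(rec$sweeps)) {
    stop("nothing to write: 'rec' must be a non-empty recording", call. = FALSE)
  }
  dialect <- match.arg(dialect)
  n <- length(rec$sweeps[[1L]]$samples)
  if (any(vapply(rec$sweeps, function(s) length(s$samples), integer(1)) != n)) {
    stop("all sweeps must have equal length to share one table", call. = FALSE)
  }
  si <- rec$sweeps[[1L]]$sample_interval
  tm <- (seq_len(n) - 1L) * si
  cols <- c(list(time_ms = sprintf("%.8g", tm)),
            lapply(rec$sweeps, function(s) sprintf("%.8g", s$samples)))
  names(cols)[-1L] <- sprintf("sweep_%04d", seq_along(rec$sweeps))
  tab <- as.data.frame(cols, check.names = FALSE)
  if (dialect == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ATF\t1.0",
                 sprintf("%d\t%d", 1L, ncol(tab)),
                 sprintf("\"SweepCount=%d\"", length(rec$sweeps)),
                 paste(names(tab), collapse = "\t")), con)
    utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  meta <- list(
    stimulus_times = lapply(rec$sweeps, `[[`, "stimulus_times"),
    intensities = vapply(rec$sweeps, `[[`, numeric(1), "stimulus_intensity"),
    t_acquired = vapply(rec$sweeps, `[[`, numeric(1), "t_acquired"),
    phase = vapply(rec$sweeps, function(s) s$meta$phase %||% NA_character_,
                   character(1)),
    t_post_tbs = vapply(rec$sweeps, function(s) s$meta$t_post_tbs %||% NA_real_,
                        numeric(1)),
    inter_sweep_interval = if (is.null(rec$protocol)) 10
                           else rec$protocol$inter_sweep_interval,
    label = rec$label, slice_id = rec$slice_id, animal_id = rec$animal_id,
    protocol = if (is.null(rec$protocol)) NULL else
      rec$protocol[c("kind", "pulse_times", "intensities", "isi")]
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
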