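# End-to-end cohort pipeline: simulate n slices per condition, run every
# analysis (input-output, paired pulse, LTP, tetanus AUC, mCBI), apply the
# baseline-stability inclusion rule, and compare the groups.

#' Simulate and analyze one slice
#'
#' Runs the full per-slice workflow on simulated data: an input-output ramp
#' (33 intensities x 6 sweeps), selection of the intensity giving ~50 % of
#' the maximal slope, a paired-pulse series, and an LTP experiment whose
#' theta-burst episode also yields the tetanus AUC and the mCBI.
#'
#' @param params A [sim_params()] object (see [preset()]).
#' @param config An [analysis_config()].
#' @param slice_id,animal_id,label Identifiers for the outputs.
#' @return A `fieldlab_slice`: list with `io`, `ppr`, `ltp`, `auc`,
#'   `mcbi` (per-burst values and mean), `summary` (one-row data frame),
#'   and the chosen `baseline_intensity`.
#' @export
analyze_slice <- function(params, config = analysis_config(),
                          slice_id = NA_character_, animal_id = NA_character_,
                          label = NA_character_) {
  simcfg <- config$simulation
  io_rec <- simulate_experiment(
    params, build_io_ramp(simcfg$io_max_intensity, simcfg$io_step,
                          simcfg$sweeps_per_intensity,
                          simcfg$inter_sweep_interval),
    label = label, slice_id = slice_id, animal_id = animal_id)
  io <- analyze_io(io_rec, config, expected_sweeps = simcfg$sweeps_per_intensity)
  i_half <- halfmax_intensity(io)

  ppr_params <- params
  ppr_params$seed <- derive_seed(params$seed, 2L)
  ppr_rec <- simulate_experiment(
    ppr_params, build_paired_pulse(i_half, isi = simcfg$isi,
                                   n_sweeps = simcfg$ppr_sweeps,
                                   inter_sweep_interval = simcfg$inter_sweep_interval),
    label = label, slice_id = slice_id, animal_id = animal_id)
  ppr <- analyze_ppr(ppr_rec, config)

  ltp_params <- params
  ltp_params$seed <- derive_seed(params$seed, 3L)
  ltp_rec <- simulate_experiment(
    ltp_params, build_ltp_protocol(i_half, simcfg$baseline_min,
                                   simcfg$followup_min,
                                   simcfg$inter_sweep_interval),
    label = label, slice_id = slice_id, animal_id = animal_id)
  ltp <- analyze_ltp(ltp_rec, config)

  is_tbs <- vapply(ltp_rec$sweeps, function(s) identical(s$meta$phase, "tbs"),
                   logical(1))
  tbs_sweeps <- ltp_rec$sweeps[is_tbs]
  auc <- tetanus_depolarization(tbs_sweeps, config)
  mcbi_per_burst <- vapply(tbs_sweeps, function(s)
    as.numeric(compute_mcbi(s, config$windows$mcbi_window)), numeric(1))

  summary_row <- data.frame(
    label = label, slice_id = slice_id, animal_id = animal_id,
    io_max_slope = io$curve$mean_slope[nrow(io$curve)],
    io_max_fv = io$curve$mean_fv[nrow(io$curve)],
    ppr = ppr$ppr,
    ltp = ltp$ltp_magnitude,
    auc = auc$mean_auc,
    mcbi = mean(mcbi_per_burst),
    baseline_fv = ltp$baseline_fv,
    baseline_intensity = i_half,
    included = ltp$included,
    variance_pct = ltp$variance_pct
  )
  structure(list(io = io, ppr = ppr, ltp = ltp, auc = auc,
                 mcbi = list(per_burst = mcbi_per_burst,
                             mean = mean(mcbi_per_burst)),
                 baseline_intensity = i_half, summary = summary_row),
            class = "fieldlab_slice")
}

underpowered_comparison <- function(label_a, label_b) {
  structure(list(label_a = label_a, label_b = label_b,
                 t_stat = NA_real_, df = NA_real_, p_two_tailed = NA_real_,
                 underpowered = TRUE),
            class = "fieldlab_comparison")
}

#' Run a full simulated cohort
#'
#' Simulates `n_per_group` slices per condition with per-slice seeds
#' derived deterministically from `seed`, runs all analyses, applies the
#' baseline-stability inclusion rule to the LTP-derived metrics, and
#' compares the groups (Grubbs pre-screen then Welch test) on the six
#' headline metrics: maximal input-output slope, maximal fiber volley,
#' paired-pulse ratio, LTP magnitude, tetanus AUC, and mCBI (normalized to
#' the first group's mean). With `n_per_group = 1` the pipeline runs but
#' comparisons are marked underpowered.
#'
#' @param n_per_group Slices per condition.
#' @param seed Master seed; all randomness derives from it.
#' @param config An [analysis_config()].
#' @param conditions Two [preset()] condition names.
#' @param slice_cv Between-slice variability: lognormal coefficient of
#'   variation applied to recruitment (`fv_max`) and synaptic gain.
#' @return A `fieldlab_cohort`: list with `per_slice` (data frame),
#'   `comparisons` (named list of `fieldlab_comparison`), `io_curves`,
#'   `timecourse` (minute-binned normalized slope per condition), `seed`,
#'   `config`, and `slices`.
#' @export
run_cohort <- function(n_per_group = 6, seed = 1L, config = analysis_config(),
                       conditions = c("air", "hyperoxia"), slice_cv = 0.10) {
  stopifnot(length(conditions) == 2L, n_per_group >= 1)
  slices <- list()
  rows <- list()
  for (ci in seq_along(conditions)) {
    for (si in seq_len(n_per_group)) {
      slice_seed <- derive_seed(seed, ci, si)
      jit <- withr::with_seed(derive_seed(slice_seed, 99L),
                              exp(stats::rnorm(2L, 0, slice_cv)))
      params <- preset(conditions[ci], seed = slice_seed)
      params$fv_max <- params$fv_max * jit[1L]
      params$syn_gain <- params$syn_gain * jit[2L]
      sl <- analyze_slice(params, config,
                          slice_id = sprintf("%s_%02d", conditions[ci], si),
                          animal_id = sprintf("animal_%s_%02d", conditions[ci], si),
                          label = conditions[ci])
      slices[[length(slices) + 1L]] <- sl
      rows[[length(rows) + 1L]] <- sl$summary
    }
  }
  per_slice <- do.call(rbind, rows)
  rownames(per_slice) <- NULL

  a <- conditions[1L]
  b <- conditions[2L]
  grp <- function(metric, lab, only_included = FALSE) {
    sel <- per_slice$label == lab
    if (only_included) sel <- sel & per_slice$included
    per_slice[[metric]][sel]
  }
  if (any(!per_slice$included)) {
    for (lab in conditions) {
      if (!any(per_slice$included[per_slice$label == lab])) {
        bad <- per_slice[per_slice$label == lab, c("slice_id", "variance_pct")]
        stop("all '", lab, "' slices excluded by the baseline-stability rule:\n",
             paste(sprintf("  %s: %.2f%%", bad$slice_id, bad$variance_pct),
                   collapse = "\n"), call. = FALSE)
      }
    }
  }
  # mCBI is reported relative to the first (control) group's mean
  mcbi_ref <- mean(grp("mcbi", a, only_included = TRUE))
  per_slice$mcbi_norm <- normalize_metric(per_slice$mcbi, mcbi_ref)

  cmp <- function(metric, only_included = FALSE) {
    va <- grp(metric, a, only_included)
    vb <- grp(metric, b, only_included)
    if (length(va) < 2L || length(vb) < 2L) {
      return(underpowered_comparison(a, b))
    }
    compare_groups(va, vb, label_a = a, label_b = b,
                   alpha = config$stats$alpha,
                   grubbs_screen = config$stats$grubbs_screen)
  }
  comparisons <- list(
    io_max_slope = cmp("io_max_slope"),
    io_max_fv = cmp("io_max_fv"),
    ppr = cmp("ppr"),
    ltp = cmp("ltp", only_included = TRUE),
    auc = cmp("auc", only_included = TRUE),
    mcbi = cmp("mcbi_norm", only_included = TRUE),
    baseline_fv = cmp("baseline_fv", only_included = TRUE)
  )

  io_curves <- do.call(rbind, lapply(conditions, function(lab) {
    curves <- lapply(slices[per_slice$label == lab], function(s) s$io$curve)
    ref <- curves[[1L]]
    data.frame(label = lab, intensity = ref$intensity,
               mean_slope = rowMeans(sapply(curves, `[[`, "mean_slope")),
               mean_fv = rowMeans(sapply(curves, `[[`, "mean_fv")))
  }))
  timecourse <- do.call(rbind, lapply(conditions, function(lab) {
    keep <- per_slice$label == lab & per_slice$included
    tcs <- lapply(slices[keep], function(s) s$ltp$timecourse)
    ref <- tcs[[1L]]
    data.frame(label = lab, t_min = ref$t_min,
               normalized_slope = rowMeans(sapply(tcs, `[[`, "normalized_slope")))
  }))

  structure(list(per_slice = per_slice, comparisons = comparisons,
                 io_curves = io_curves, timecourse = timecourse,
                 seed = seed, n_per_group = n_per_group,
                 conditions = conditions, config = config, slices = slices),
            class = "fieldlab_cohort")
}

#' @export
print.fieldlab_cohort <- function(x, ...) {
  cat(sprintf("<fieldlab_cohort> %s vs %s, n = %d/%d, seed = %s\n",
              x$conditions[1L], x$conditions[2L],
              sum(x$per_slice$label == x$conditions[1L]),
              sum(x$per_slice$label == x$conditions[2L]), format(x$seed)))
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    if (isTRUE(cc$underpowered)) {
      cat(sprintf("  %-14s underpowered (n < 2 per group)\n", nm))
    } else {
      cat(sprintf("  %-14s %8.4g vs %8.4g   p = %.3g\n",
                  nm, cc$mean_a, cc$mean_b, cc$p_two_tailed))
    }
  }
  invisible(x)
}

comparison_row <- function(name, cc) {
  if (isTRUE(cc$underpowered)) {
    return(data.frame(metric = name, mean_a = NA_real_, se_a = NA_real_,
                      n_a = NA_integer_, mean_b = NA_real_, se_b = NA_real_,
                      n_b = NA_integer_, t = NA_real_, df = NA_real_,
                      p = NA_real_, removed_a = 0L, removed_b = 0L))
  }
  data.frame(metric = name, mean_a = cc$mean_a, se_a = cc$se_a, n_a = cc$n_a,
             mean_b = cc$mean_b, se_b = cc$se_b, n_b = cc$n_b,
             t = cc$t_stat, df = cc$df, p = cc$p_two_tailed,
             removed_a = length(cc$removed_a), removed_b = length(cc$removed_b))
}

#' Write a cohort results bundle to disk
#'
#' Emits the summary tables (CSV) and overview figures (PNG) for a cohort:
#' input-output curves for slope and fiber volley, a paired-pulse summary,
#' the LTP time course with the analysis window shaded, and tetanus
#' AUC / mCBI summaries, plus a JSON run manifest. Table values are written
#' at full precision, identical to the in-memory bundle.
#'
#' @param bundle A `fieldlab_cohort` from [run_cohort()].
#' @param out_dir Output directory (created if absent).
#' @param figures Write PNG figures? (default TRUE)
#' @return Invisibly, the paths written.
#' @export
report <- function(bundle, out_dir, figures = TRUE) {
  stopifnot(inherits(bundle, "fieldlab_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$per_slice, "per_slice_metrics.csv")
  wr(do.call(rbind, Map(comparison_row, names(bundle$comparisons),
                        bundle$comparisons)),
     "group_comparisons.csv")
  wr(bundle$io_curves, "io_curves.csv")
  if (is.null(bundle$timecourse) || !nrow(bundle$timecourse)) {
    warning("empty LTP timecourse; table omitted", call. = FALSE)
  } else {
    wr(bundle$timecourse, "ltp_timecourse.csv")
  }
  ppr_tab <- bundle$per_slice[, c("label", "slice_id", "ppr")]
  wr(ppr_tab, "ppr_summary.csv")
  wr(bundle$per_slice[, c("label", "slice_id", "auc", "mcbi", "mcbi_norm")],
     "auc_mcbi_summary.csv")

  if (figures) {
    lab_a <- bundle$conditions[1L]
    gg_bar <- function(metric, ylab) {
      df <- bundle$per_slice
      ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data[[metric]])) +
        ggplot2::stat_summary(fun = mean, geom = "col", width = 0.6,
                              ggplot2::aes(fill = .data$label)) +
        ggplot2::geom_jitter(width = 0.08, size = 1.5) +
        ggplot2::labs(x = NULL, y = ylab) +
        ggplot2::theme_classic() +
        ggplot2::theme(legend.position = "none")
    }
    save_fig <- function(plot, name, w = 4.5, h = 3.5) {
      p <- file.path(out_dir, name)
      ggplot2::ggsave(p, plot, width = w, height = h, dpi = 100)
      paths <<- c(paths, p)
    }
    save_fig(
      ggplot2::ggplot(bundle$io_curves,
                      ggplot2::aes(.data$intensity, .data$mean_slope,
                                   colour = .data$label)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "stimulus intensity (uA)",
                      y = "fEPSP slope (mV/ms)") +
        ggplot2::theme_classic(),
      "fig_io_slope.png")
    save_fig(
      ggplot2::ggplot(bundle$io_curves,
                      ggplot2::aes(.data$intensity, .data$mean_fv,
                                   colour = .data$label)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
        ggplot2::labs(x = "stimulus intensity (uA)",
                      y = "fiber volley (mV)") +
        ggplot2::theme_classic(),
      "fig_io_fv.png")
    save_fig(gg_bar("ppr", "paired-pulse ratio"), "fig_ppr.png")
    win <- bundle$config$windows$ltp_window
    save_fig(
      ggplot2::ggplot(bundle$timecourse,
                      ggplot2::aes(.data$t_min, .data$normalized_slope,
                                   colour = .data$label)) +
        ggplot2::annotate("rect", xmin = win[1L], xmax = win[2L],
                          ymin = -Inf, ymax = Inf, alpha = 0.15) +
        ggplot2::geom_hline(yintercept = 100, linetype = 2) +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::labs(x = "time from tetanus (min)",
                      y = "fEPSP slope (% baseline)") +
        ggplot2::theme_classic(),
      "fig_ltp_timecourse.png", w = 6)
    excit <- rbind(
      data.frame(label = bundle$per_slice$label, metric = "tetanus AUC (mV.ms)",
                 value = bundle$per_slice$auc),
      data.frame(label = bundle$per_slice$label,
                 metric = sprintf("mCBI (rel. %s mean)", lab_a),
                 value = bundle$per_slice$mcbi_norm))
    save_fig(
      ggplot2::ggplot(excit, ggplot2::aes(.data$label, .data$value,
                                          fill = .data$label)) +
        ggplot2::stat_summary(fun = mean, geom = "col", width = 0.6) +
        ggplot2::geom_jitter(width = 0.08, size = 1.5, show.legend = FALSE) +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = NULL, y = NULL) +
        ggplot2::theme_classic() +
        ggplot2::theme(legend.position = "none"),
      "fig_auc_mcbi.png", w = 7)
  }

  manifest <- list(
    tool = "fieldlab",
    version = as.character(utils::packageVersion("fieldlab")),
    seed = bundle$seed,
    n_per_group = bundle$n_per_group,
    conditions = bundle$conditions,
    config = unclass(bundle$config),
    outputs = basename(paths),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}
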