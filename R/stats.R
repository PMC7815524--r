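# Group-comparison statistics: unequal-variance (Welch) two-sample t-test,
# single-outlier Grubbs screening, mean +/- SE summaries, and power of the
# two-sample t-test. Implemented directly from the textbook formulas so
# that summary-form input (n, mean, SE) is supported alongside raw samples;
# base R's t.test / power.t.test serve as independent cross-checks in the
# test suite.

#' Summarize a sample as mean and standard error
#'
#' @param values Numeric sample (n >= 2 for a standard error).
#' @param units Unit string carried along for reporting.
#' @return A `fieldlab_summary`: list with `n`, `mean`, `se`, `units`.
#' @export
group_summary <- function(values, units = "") {
  values <- as.numeric(values)
  n <- length(values)
  structure(list(n = n, mean = mean(values),
                 se = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
                 units = units),
            class = "fieldlab_summary")
}

#' @export
print.fieldlab_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.3g %s (n = %d)\n", x$mean, x$se, x$units, x$n))
  invisible(x)
}

welch_from_summaries <- function(n_a, m_a, se_a, n_b, m_b, se_b,
                                 label_a, label_b, values_a = NULL,
                                 values_b = NULL) {
  if (n_a < 2L || n_b < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (se_a == 0 && se_b == 0) {
    if (isTRUE(all.equal(m_a, m_b))) {
      t_stat <- 0; df <- n_a + n_b - 2; p <- 1
    } else {
      stop("degenerate input: zero variance in both groups with unequal means",
           call. = FALSE)
    }
  } else {
    v_a <- se_a^2
    v_b <- se_b^2
    t_stat <- (m_a - m_b) / sqrt(v_a + v_b)
    df <- (v_a + v_b)^2 / (v_a^2 / (n_a - 1) + v_b^2 / (n_b - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(label_a = label_a, label_b = label_b,
                 values_a = values_a, values_b = values_b,
                 n_a = n_a, mean_a = m_a, se_a = se_a,
                 n_b = n_b, mean_b = m_b, se_b = se_b,
                 t_stat = t_stat, df = df, p_two_tailed = p),
            class = "fieldlab_comparison")
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-tailed unpaired comparison that does not assume equal variances:
#' `t = (m_a - m_b) / sqrt(se_a^2 + se_b^2)` with Welch-Satterthwaite
#' fractional degrees of freedom. Accepts either raw samples or published
#' summaries via `welch_t_summary()`.
#'
#' @param values_a,values_b Numeric samples, each with n >= 2.
#' @return A `fieldlab_comparison`: list with group summaries, `t_stat`,
#'   fractional `df`, and `p_two_tailed`.
#' @export
#' @examples
#' welch_t(c(1.2, 1.4, 1.3), c(2.0, 2.2, 2.4))$p_two_tailed
welch_t <- function(values_a, values_b) {
  a <- group_summary(values_a)
  b <- group_summary(values_b)
  welch_from_summaries(a$n, a$mean, a$se, b$n, b$mean, b$se,
                       label_a = deparse1(substitute(values_a)),
                       label_b = deparse1(substitute(values_b)),
                       values_a = as.numeric(values_a),
                       values_b = as.numeric(values_b))
}

#' @rdname welch_t
#' @param n_a,mean_a,se_a,n_b,mean_b,se_b Published group sizes, means and
#'   standard errors.
#' @param label_a,label_b Group labels.
#' @export
welch_t_summary <- function(n_a, mean_a, se_a, n_b, mean_b, se_b,
                            label_a = "a", label_b = "b") {
  welch_from_summaries(n_a, mean_a, se_a, n_b, mean_b, se_b,
                       label_a = label_a, label_b = label_b)
}

#' @export
print.fieldlab_comparison <- function(x, ...) {
  stars <- if (x$p_two_tailed < 0.01) "**" else if (x$p_two_tailed < 0.05) "*" else ""
  cat(sprintf("%s: %.4g +/- %.3g (n=%d) vs %s: %.4g +/- %.3g (n=%d)\n",
              x$label_a, x$mean_a, x$se_a, x$n_a,
              x$label_b, x$mean_b, x$se_b, x$n_b))
  cat(sprintf("  Welch t = %.4g, df = %.3g, p = %.4g%s\n",
              x$t_stat, x$df, x$p_two_tailed, stars))
  invisible(x)
}

#' Grubbs single-outlier test
#'
#' Two-sided, single-pass Grubbs test: `G = max |v - mean| / sd`, compared
#' with the t-quantile critical value
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))`,
#' `t = qt(1 - alpha/(2n), n - 2)`. At most one value is flagged per call.
#'
#' @param values Numeric sample, n >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List with `outlier_index` (`NA` when none), `G`, `G_crit`,
#'   `alpha`, `n`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs n >= 3", call. = FALSE)
  s <- stats::sd(values)
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  if (s == 0) {
    return(list(outlier_index = NA_integer_, G = 0, G_crit = g_crit,
                alpha = alpha, n = n))
  }
  dev <- abs(values - mean(values)) / s
  g <- max(dev)
  list(outlier_index = if (g > g_crit) which.max(dev) else NA_integer_,
       G = g, G_crit = g_crit, alpha = alpha, n = n)
}

#' Power of the two-sided two-sample t-test
#'
#' Computed from the noncentral t distribution with noncentrality
#' `d * sqrt(n/2)` and `2n - 2` degrees of freedom.
#'
#' @param effect_size Standardized difference d (>= 0).
#' @param n_per_group Group size (>= 2).
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample_t <- function(effect_size, n_per_group, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (effect_size < 0 || n_per_group < 2) {
    stop("'effect_size' must be >= 0 and 'n_per_group' >= 2", call. = FALSE)
  }
  df <- 2 * n_per_group - 2
  ncp <- effect_size * sqrt(n_per_group / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

#' Compare two labeled groups with optional outlier screening
#'
#' Applies a single-pass [grubbs_test()] per group (unless disabled),
#' removes any flagged value, then runs [welch_t()]. Removed indices are
#' recorded on the result.
#'
#' @param values_a,values_b Per-slice metric values for the two groups.
#' @param label_a,label_b Group labels.
#' @param alpha Significance level for the outlier screen.
#' @param grubbs_screen Apply the Grubbs pre-screen? (default TRUE)
#' @return A `fieldlab_comparison` with elements `removed_a` / `removed_b`
#'   (integer indices, possibly empty).
#' @export
compare_groups <- function(values_a, values_b, label_a = "a", label_b = "b",
                           alpha = 0.05, grubbs_screen = TRUE) {
  removed_a <- integer()
  removed_b <- integer()
  if (grubbs_screen) {
    if (length(values_a) >= 3L) {
      g <- grubbs_test(values_a, alpha)
      if (!is.na(g$outlier_index)) removed_a <- g$outlier_index
    }
    if (length(values_b) >= 3L) {
      g <- grubbs_test(values_b, alpha)
      if (!is.na(g$outlier_index)) removed_b <- g$outlier_index
    }
  }
  keep_a <- if (length(removed_a)) values_a[-removed_a] else values_a
  keep_b <- if (length(removed_b)) values_b[-removed_b] else values_b
  if (length(keep_a) < 2L || length(keep_b) < 2L) {
    stop("a group has fewer than 2 values after outlier removal", call. = FALSE)
  }
  sa <- group_summary(keep_a)
  sb <- group_summary(keep_b)
  out <- welch_from_summaries(sa$n, sa$mean, sa$se, sb$n, sb$mean, sb$se,
                              label_a = label_a, label_b = label_b,
                              values_a = keep_a, values_b = keep_b)
  out$removed_a <- removed_a
  out$removed_b <- removed_b
  out
}
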