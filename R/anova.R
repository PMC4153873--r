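#' One-way ANOVA from per-group summary statistics
#'
#' Computes the fixed-effects one-way ANOVA decomposition from group sample
#' sizes, means, and SDs alone; no raw observations are needed. With group
#' sizes n_i, means m_i, and SDs s_i (N = sum n_i, grand mean
#' g = sum n_i m_i / N):
#'
#' \deqn{SS_B = \sum n_i (m_i - g)^2, \quad SS_W = \sum (n_i - 1) s_i^2}
#'
#' with df k-1 and N-k, mean squares MS = SS/df, F = MS_B/MS_W, and the
#' p-value the upper tail of F(k-1, N-k). The mean square within (MSE) is the
#' pooled within-group variance reused by every post-hoc procedure. The
#' pooled SEM is sqrt(MSE/n) for balanced designs; for unbalanced designs n
#' is replaced by the harmonic mean of the group sizes, matching the
#' convention of the studentized-range tests.
#'
#' Degenerate input: if every SD is zero and all means are equal the F
#' statistic is undefined (0/0); the result carries `f_stat = NA`, `p_value
#' = 1` and a warning. Zero within-group variance with unequal means is an
#' error, since no finite F exists.
#'
#' @param summary A [response_summary()].
#' @return An object of class `anova_result`: list with `k`, `N`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `ms_between`,
#'   `ms_within`, `f_stat`, `p_value`, `mse`, `pooled_sem`, `grand_mean`.
#' @examples
#' rs <- response_summary("Arginine", c("0", "4", "8"), 6,
#'                        c(110, 115, 149), c(4, 5, 6), "SEM")
#' anova_from_summary(rs)  # F = 17.55 on (2, 15) df
#' @export
anova_from_summary <- function(summary) {
  stopifnot(inherits(summary, "response_summary"))
  g <- summary$groups
  k <- nrow(g)
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  ss_between <- sum(g$n * (g$mean - grand)^2)
  ss_within <- sum((g$n - 1) * g$sd^2)
  df_between <- k - 1
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  if (ms_within <= 0) {
    if (ss_between > 0)
      stop("zero within-group variance: all SDs are zero but group means differ")
    warning("degenerate input: all SDs zero and all means equal; F undefined")
    f_stat <- NA_real_
    p_value <- 1
  } else {
    f_stat <- ms_between / ms_within
    p_value <- stats::pf(f_stat, df_between, df_within, lower.tail = FALSE)
  }
  balanced <- length(unique(g$n)) == 1L
  n_h <- if (balanced) g$n[1] else k / sum(1 / g$n)
  structure(list(
    k = k, N = N,
    df_between = df_between, df_within = df_within,
    ss_between = ss_between, ss_within = ss_within,
    ms_between = ms_between, ms_within = ms_within,
    f_stat = f_stat, p_value = p_value,
    mse = ms_within,
    pooled_sem = if (ms_within > 0) sqrt(ms_within / n_h) else 0,
    grand_mean = grand
  ), class = "anova_result")
}

#' One-way ANOVA from raw observations
#'
#' Convenience composition [summarize_raw()] then [anova_from_summary()]:
#' the raw and summary input paths share one computation, so the two are
#' exactly equivalent on complete data.
#'
#' @inheritParams summarize_raw
#' @return An `anova_result`; see [anova_from_summary()].
#' @examples
#' anova_from_raw(rep(c("A", "B"), each = 3), c(1, 2, 3, 2, 3, 4))
#' @export
anova_from_raw <- function(factor_values, response_values,
                           variable = "response") {
  anova_from_summary(summarize_raw(factor_values, response_values, variable))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s\n",
              x$df_between, x$df_within,
              if (is.na(x$f_stat)) "NA" else format(x$f_stat, digits = 5),
              format(x$p_value, digits = 4)))
  cat(sprintf("  MSE = %s, pooled SEM = %s\n",
              format(x$mse, digits = 5), format(x$pooled_sem, digits = 5)))
  invisible(x)
}
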