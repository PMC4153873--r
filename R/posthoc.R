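#' All-pairwise multiple comparison procedures
#'
#' Four classical procedures over the pooled within-group variance (MSE) of a
#' one-way ANOVA: Fisher's LSD with optional family-wise p-value adjustment,
#' the single-step Tukey-Kramer test, and the stepwise Student-Newman-Keuls
#' (SNK) and Duncan multiple range tests. All return an `mcp_result` holding
#' every pairwise comparison and a symmetric boolean significance relation,
#' the input consumed by the compact-letter-display builder.
#'
#' @name posthoc
NULL

# Shared validation + skeleton for all four tests.
mcp_prepare <- function(summary, anova, alpha) {
  stopifnot(inherits(summary, "response_summary"),
            inherits(anova, "anova_result"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (anova$df_within < 1) stop("df_within must be >= 1")
  if (!is.finite(anova$mse) || anova$mse <= 0)
    stop("zero within-group variance: post-hoc comparisons are undefined")
  g <- summary$groups
  if (nrow(g) != anova$k || sum(g$n) != anova$N)
    stop("anova result does not match the summary it was computed from")
  g
}

mcp_result <- function(method, adjust, alpha, labels, comparisons) {
  k <- length(labels)
  relation <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (r in seq_len(nrow(comparisons))) {
    i <- comparisons$label_i[r]; j <- comparisons$label_j[r]
    relation[i, j] <- relation[j, i] <- comparisons$significant[r]
  }
  structure(list(method = method, adjust = adjust, alpha = alpha,
                 labels = labels, comparisons = comparisons,
                 relation = relation),
            class = "mcp_result")
}

#' @export
print.mcp_result <- function(x, ...) {
  cat(sprintf("%s multiple comparisons (alpha = %g%s)\n", x$method, x$alpha,
              if (x$adjust != "none") paste0(", ", x$adjust, " adjustment") else ""))
  print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Family-wise p-value adjustment
#'
#' Bonferroni multiplies each p-value by the family size m and caps at 1.
#' Holm is the step-down refinement: sort ascending, multiply the i-th
#' smallest by (m - i + 1), enforce a running maximum so the output is
#' monotone in the input ranks, cap at 1, and restore the original order.
#' Holm is never larger than Bonferroni and both are never smaller than the
#' raw p-values.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values in the input order.
#' @examples
#' adjust_pvalues(c(0.01, 0.04, 0.03), "holm")  # 0.03 0.06 0.06
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}

#' Fisher's least significant difference test
#'
#' Pairwise t-tests on the pooled MSE: for groups i, j the statistic is
#' t = (m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j)) referred to t(df_within),
#' two-sided. Unadjusted LSD controls the family-wise error rate only weakly
#' (strongly for k = 3); `adjust = "bonferroni"` or `"holm"` applies
#' [adjust_pvalues()] across the family of all k(k-1)/2 pairs. A pair is
#' significant when its (adjusted) p-value is at most `alpha`.
#'
#' @param summary A [response_summary()].
#' @param anova The matching [anova_from_summary()] result.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"`, `"bonferroni"`, or `"holm"`.
#' @return An `mcp_result`.
#' @export
lsd_test <- function(summary, anova, alpha = 0.05,
                     adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  g <- mcp_prepare(summary, anova, alpha)
  pairs <- utils::combn(nrow(g), 2)
  est <- g$mean[pairs[1, ]] - g$mean[pairs[2, ]]
  se <- sqrt(anova$mse * (1 / g$n[pairs[1, ]] + 1 / g$n[pairs[2, ]]))
  tval <- est / se
  p_raw <- 2 * stats::pt(-abs(tval), anova$df_within)
  p_adj <- if (adjust == "none") p_raw else adjust_pvalues(p_raw, adjust)
  comparisons <- data.frame(
    label_i = g$label[pairs[1, ]], label_j = g$label[pairs[2, ]],
    estimate = est, std_error = se, statistic = tval,
    span = 2L, p_raw = p_raw, p_adjusted = p_adj,
    significant = p_adj <= alpha, stringsAsFactors = FALSE)
  mcp_result("LSD", adjust, alpha, g$label, comparisons)
}

#' Tukey-Kramer (Tukey HSD) test
#'
#' Single-step studentized-range test with the Kramer generalization to
#' unequal group sizes: q = |m_i - m_j| / sqrt((MSE/2)(1/n_i + 1/n_j)),
#' with the adjusted p-value the upper tail of the studentized range
#' distribution with parameters (k, df_within). Controls the family-wise
#' error rate in the strong sense, at some cost in power.
#'
#' @inheritParams lsd_test
#' @return An `mcp_result`.
#' @export
tukey_kramer <- function(summary, anova, alpha = 0.05) {
  g <- mcp_prepare(summary, anova, alpha)
  k <- nrow(g)
  pairs <- utils::combn(k, 2)
  est <- g$mean[pairs[1, ]] - g$mean[pairs[2, ]]
  se_q <- sqrt((anova$mse / 2) * (1 / g$n[pairs[1, ]] + 1 / g$n[pairs[2, ]]))
  q <- abs(est) / se_q
  p_adj <- stats::ptukey(q, k, anova$df_within, lower.tail = FALSE)
  comparisons <- data.frame(
    label_i = g$label[pairs[1, ]], label_j = g$label[pairs[2, ]],
    estimate = est, std_error = se_q * sqrt(2), statistic = q,
    span = k, p_raw = p_adj, p_adjusted = p_adj,
    significant = p_adj <= alpha, stringsAsFactors = FALSE)
  mcp_result("TK", "none", alpha, g$label, comparisons)
}

#' Student-Newman-Keuls multiple range test
#'
#' Stepwise studentized-range test. Means are ordered (descending); a pair
#' whose difference spans r ordered means is compared against the critical
#' range q(alpha; r, df_within) * sqrt(MSE / n_h), where n_h is the harmonic
#' mean of the sizes of the groups in the span. Spans are examined
#' widest-first: when a span's extreme difference fails its critical range,
#' every pair inside that span is declared not significant without further
#' testing (the blocking rule that keeps the stepwise procedure coherent).
#'
#' Pairwise p-values are reported for information only — the upper tail of
#' the span-r range distribution at the observed q — and are not
#' family-wise-calibrated; the normative output is the decision in
#' `significant` (and the critical range in `critical_range`).
#' `p_adjusted` is `NA` for this test.
#'
#' @inheritParams lsd_test
#' @return An `mcp_result` whose `comparisons` gains a `critical_range`
#'   column.
#' @export
snk_test <- function(summary, anova, alpha = 0.05) {
  range_test(summary, anova, alpha, method = "SNK")
}

#' Duncan's multiple range test
#'
#' Identical mechanics to [snk_test()] except that the span-r comparison
#' uses the relaxed protection level alpha_r = 1 - (1 - alpha)^(r - 1), so
#' its critical ranges never exceed SNK's and Duncan rejects at least every
#' pair SNK rejects.
#'
#' @inheritParams lsd_test
#' @return An `mcp_result` with a `critical_range` column.
#' @export
duncan_test <- function(summary, anova, alpha = 0.05) {
  range_test(summary, anova, alpha, method = "DC")
}

# Shared engine for the two multiple range tests. Works in the space of
# means sorted descending (stable, so ties keep input order), then maps
# decisions back to input-order labels.
range_test <- function(summary, anova, alpha, method = c("SNK", "DC")) {
  method <- match.arg(method)
  g <- mcp_prepare(summary, anova, alpha)
  k <- nrow(g)
  ord <- order(-g$mean)  # stable in base R
  gm <- g[ord, ]
  dfw <- anova$df_within
  sig <- matrix(NA, k, k)        # in sorted space, upper triangle used
  crit_used <- matrix(NA_real_, k, k)
  nonsig_spans <- matrix(numeric(0), ncol = 2)
  for (r in seq(k, 2)) {
    a_r <- if (method == "DC") 1 - (1 - alpha)^(r - 1) else alpha
    qcrit <- stats::qtukey(1 - a_r, r, dfw)
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      blocked <- nrow(nonsig_spans) > 0 &&
        any(nonsig_spans[, 1] <= i & j <= nonsig_spans[, 2])
      n_h <- (j - i + 1) / sum(1 / gm$n[i:j])
      crange <- qcrit * sqrt(anova$mse / n_h)
      crit_used[i, j] <- crange
      if (blocked) {
        sig[i, j] <- FALSE
      } else {
        diff <- gm$mean[i] - gm$mean[j]
        if (abs(diff) > crange) {
          sig[i, j] <- TRUE
        } else {
          sig[i, j] <- FALSE
          nonsig_spans <- rbind(nonsig_spans, c(i, j))
        }
      }
    }
  }
  pairs <- utils::combn(k, 2)  # in input order
  pos <- match(seq_len(k), ord)  # input index -> sorted position
  rows <- lapply(seq_len(ncol(pairs)), function(c0) {
    a <- pairs[1, c0]; b <- pairs[2, c0]
    i <- min(pos[a], pos[b]); j <- max(pos[a], pos[b])
    r <- j - i + 1
    n_h <- r / sum(1 / gm$n[i:j])
    se <- sqrt(anova$mse / n_h)
    qv <- abs(g$mean[a] - g$mean[b]) / se
    data.frame(
      label_i = g$label[a], label_j = g$label[b],
      estimate = g$mean[a] - g$mean[b], std_error = se, statistic = qv,
      span = r,
      p_raw = stats::ptukey(qv, r, dfw, lower.tail = FALSE),
      p_adjusted = NA_real_,
      critical_range = crit_used[i, j],
      significant = sig[i, j], stringsAsFactors = FALSE)
  })
  mcp_result(method, "none", alpha, g$label, do.call(rbind, rows))
}
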