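#' Analyze one response: ANOVA, post-hoc test, letter display
#'
#' The per-response unit of the pipeline. Runs the omnibus one-way ANOVA,
#' the chosen all-pairwise comparison procedure, and converts the resulting
#' significance relation to a compact letter display with 'a' attached to
#' the class containing the largest mean.
#'
#' By default the post-hoc test runs regardless of the omnibus outcome
#' (published tables are usually produced this way, and the stepwise range
#' tests carry their own protection). With `protected = TRUE` the classical
#' two-step procedure is enforced: when the omnibus p-value exceeds `alpha`,
#' all pairs are declared not significant and the row gets a single letter
#' class.
#'
#' @param summary A [response_summary()].
#' @param test `"lsd"`, `"tukey"`, `"snk"`, or `"duncan"`.
#' @param alpha Significance level (default 0.05).
#' @param adjust p-value adjustment for the LSD test (`"none"`,
#'   `"bonferroni"`, `"holm"`); rejected for the other tests, which carry
#'   their own multiplicity control.
#' @param protected Suppress post-hoc significance when the omnibus test
#'   does not reject (default `FALSE`).
#' @return List with `summary`, `anova`, `mcp`, `cld`.
#' @export
analyze_response <- function(summary, test = c("lsd", "tukey", "snk", "duncan"),
                             alpha = 0.05,
                             adjust = c("none", "bonferroni", "holm"),
                             protected = FALSE) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (adjust != "none" && test != "lsd")
    stop("p-value adjustment applies to the LSD test only; test '", test,
         "' has its own multiplicity control")
  anova <- anova_from_summary(summary)
  k <- anova$k
  labels <- summary$groups$label
  degenerate <- is.na(anova$f_stat)
  if (degenerate || (protected && anova$p_value > alpha)) {
    mcp <- NULL
    relation <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  } else {
    mcp <- switch(test,
                  lsd = lsd_test(summary, anova, alpha, adjust),
                  tukey = tukey_kramer(summary, anova, alpha),
                  snk = snk_test(summary, anova, alpha),
                  duncan = duncan_test(summary, anova, alpha))
    relation <- mcp$relation
  }
  ranks <- rank(-summary$groups$mean, ties.method = "first")
  cld <- insert_absorb(labels, relation, ranks = ranks)
  list(summary = summary, anova = anova, mcp = mcp, cld = cld)
}

#' Analyze every response of a dataset bundle
#'
#' Raw bundles are reduced to per-group summaries first (see
#' [summarize_raw()]); summary bundles are analyzed directly, so both input
#' paths share one computation.
#'
#' @param bundle A `dataset_bundle` from [read_workbook()].
#' @inheritParams analyze_response
#' @return List of [analyze_response()] results, one per response.
#' @export
analyze_bundle <- function(bundle, test = "snk", alpha = 0.05,
                           adjust = "none", protected = FALSE) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  summaries <- if (bundle$mode == "raw") {
    fac <- bundle$data[[bundle$factor_name]]
    lapply(bundle$responses, function(v)
      summarize_raw(fac, bundle$data[[v]], variable = v,
                    digits = bundle$raw_digits))
  } else {
    bundle$summaries
  }
  lapply(summaries, analyze_response, test = test, alpha = alpha,
         adjust = adjust, protected = protected)
}

#' Run the full workbook-to-table pipeline
#'
#' Reads a workbook, analyzes every dataset and every response in it, and
#' writes one publication-ready RTF table per dataset (optionally with a
#' TSV mirror alongside). This is the engine behind the command-line
#' interface.
#'
#' @inheritParams read_workbook
#' @inheritParams analyze_response
#' @param output_dir Directory for the output files (created if missing).
#' @param mode Table format: `"per_group_sem"` or `"pooled_sem"`.
#' @param mirror Also write a `.tsv` mirror per table (default `TRUE`).
#' @param verbose Log per-response F and p to standard error.
#' @return Invisibly, a list per dataset with `name`, `table`
#'   (`table_spec`), `results`, `rtf_path`, `tsv_path`.
#' @examples
#' \donttest{
#' cfg <- fixture_config(seed = 42)
#' wb <- file.path(tempdir(), "toy.xlsx")
#' make_raw_workbook(cfg, wb)
#' run_tables(wb, scenario = "S1", factor_name = "group", test = "snk",
#'            output_dir = tempdir())
#' }
#' @export
run_tables <- function(path, scenario = c("S1", "S2", "S3", "S4"),
                       factor_name = NULL, test = c("lsd", "tukey", "snk", "duncan"),
                       alpha = 0.05, adjust = c("none", "bonferroni", "holm"),
                       mode = c("per_group_sem", "pooled_sem"),
                       dispersion_kind = c("SEM", "SD"), sizes_spec = NULL,
                       protected = FALSE, output_dir = ".", mirror = TRUE,
                       raw_digits = 2L, verbose = FALSE) {
  scenario <- match.arg(scenario)
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  mode <- match.arg(mode)
  if (adjust != "none" && test != "lsd")
    stop("p-value adjustment applies to the LSD test only")
  wb <- read_workbook(path, scenario, factor_name = factor_name,
                      dispersion_kind = dispersion_kind,
                      sizes_spec = sizes_spec, raw_digits = raw_digits)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  test_label <- c(lsd = "LSD", tukey = "Tukey-Kramer", snk = "SNK",
                  duncan = "Duncan")[[test]]
  if (adjust != "none") test_label <- paste0(test_label, " (", adjust, ")")
  out <- lapply(wb$sheets, function(bundle) {
    results <- analyze_bundle(bundle, test = test, alpha = alpha,
                              adjust = adjust, protected = protected)
    if (verbose) for (res in results)
      message(sprintf("%s / %s: F(%d, %d) = %.4g, p = %.4g [%s]",
                      bundle$name, res$summary$variable,
                      res$anova$df_between, res$anova$df_within,
                      res$anova$f_stat, res$anova$p_value, test_label))
    tab <- build_table(results, mode = mode, alpha = alpha,
                       test_name = test_label,
                       title = paste0("One-way ANOVA results: ", bundle$name))
    stem <- file.path(output_dir, paste0(
      tools::file_path_sans_ext(basename(path)), "_", bundle$name))
    rtf_path <- paste0(stem, ".rtf")
    write_rtf(tab, rtf_path)
    tsv_path <- NULL
    if (mirror) {
      tsv_path <- paste0(stem, ".tsv")
      write_text(tab, tsv_path, dialect = "tsv")
    }
    list(name = bundle$name, table = tab, results = results,
         rtf_path = rtf_path, tsv_path = tsv_path)
  })
  invisible(out)
}
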