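#' Configuration for synthetic workbook generation
#'
#' The generator realizes exactly the model one-way ANOVA assumes: for each
#' response, observations in group i are drawn as `group_effects[i] +
#' Normal(0, sigma)`, independently across responses. Defaults emulate the
#' toy single-dataset workbook used throughout the package's documentation:
#' one factor ("group") with four levels A-D and six responses V1-V6.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param k Number of groups (>= 2).
#' @param n Per-group sample sizes (single value recycled; each >= 2).
#' @param group_effects True group means (length `k`). The default spreads
#'   the means by 0, 0.5, 1 and 2 within-group SDs — a mix of null and
#'   strong effects, so generated tables exercise both lettered and
#'   unlettered rows.
#' @param sigma Common within-group SD (> 0).
#' @param n_responses Number of response variables.
#' @param levels Group labels (default `LETTERS[1:k]`).
#' @param factor_name Name of the factor column (default `"group"`).
#' @param n_sheets Number of datasets for the multi-sheet scenarios.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, k = 4L, n = 10L,
                           group_effects = c(0, 0.5, 1, 2)[seq_len(k)],
                           sigma = 1, n_responses = 6L,
                           levels = LETTERS[seq_len(k)],
                           factor_name = "group", n_sheets = 3L) {
  stopifnot(k >= 2L, sigma > 0, n_responses >= 1L,
            length(levels) == k, length(group_effects) == k, n_sheets >= 1L)
  n <- rep_len(as.integer(n), k)
  if (any(n < 2L)) stop("every group needs n >= 2")
  structure(list(seed = as.integer(seed), k = as.integer(k), n = n,
                 group_effects = as.numeric(group_effects),
                 sigma = as.numeric(sigma),
                 n_responses = as.integer(n_responses),
                 levels = as.character(levels),
                 factor_name = factor_name,
                 n_sheets = as.integer(n_sheets)),
            class = "fixture_config")
}

#' Generate a raw-data workbook
#'
#' Writes an XLSX workbook of raw observations (scenario S1, or S2 with
#' `n_sheets` sheets named `Data1`, `Data2`, ...) plus a sidecar TSV file
#' recording the ground truth: per sheet, response, and group, the true
#' mean, the true SD, and the exact sample moments of the generated values.
#' Output is byte-identical for identical configurations.
#'
#' @param config A [fixture_config()].
#' @param path Output path (`.xlsx`); the sidecar goes to
#'   `paste0(path, ".truth.tsv")`.
#' @param scenario `"S1"` (one sheet) or `"S2"` (multiple sheets).
#' @param start_row,start_col Where the table's header cell sits (fixtures
#'   for the off-anchor reading path).
#' @return Invisibly, a list with `path`, `truth_path`, and `truth` (data
#'   frame).
#' @export
make_raw_workbook <- function(config, path, scenario = c("S1", "S2"),
                              start_row = 1L, start_col = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  n_sheets <- if (scenario == "S1") 1L else config$n_sheets
  sheets <- list()
  truth <- list()
  for (s in seq_len(n_sheets)) {
    fac <- rep(config$levels, times = config$n)
    df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                     stats::setNames(list(fac), config$factor_name))
    for (v in seq_len(config$n_responses)) {
      y <- rep(config$group_effects, times = config$n) +
        stats::rnorm(sum(config$n), 0, config$sigma)
      vn <- paste0("V", v)
      df[[vn]] <- y
      truth[[length(truth) + 1L]] <- data.frame(
        sheet = sheet_name(s, n_sheets), response = vn,
        label = config$levels,
        n = config$n,
        true_mean = config$group_effects, true_sd = config$sigma,
        sample_mean = vapply(config$levels, function(g) mean(y[fac == g]),
                             numeric(1)),
        sample_sd = vapply(config$levels, function(g) stats::sd(y[fac == g]),
                           numeric(1)),
        stringsAsFactors = FALSE)
    }
    sheets[[sheet_name(s, n_sheets)]] <- df
  }
  write_xlsx(sheets, path, start_row = start_row, start_col = start_col)
  truth <- do.call(rbind, truth)
  truth_path <- paste0(path, ".truth.tsv")
  write_truth(truth, truth_path)
  invisible(list(path = path, truth_path = truth_path, truth = truth))
}

#' Generate a summary-data workbook
#'
#' Draws raw observations from the same model as [make_raw_workbook()],
#' reduces them to per-group summaries, and writes them in the summary
#' layout: first column the group label, then a (mean, dispersion) column
#' pair per response. Defaults emulate the toy summary workbook: two
#' responses `Var1`, `Var2` over four levels `L1`-`L4`. Scenario `"S4"`
#' writes `n_sheets` summary sheets.
#'
#' @param config A [fixture_config()]; for the summary default call
#'   `fixture_config(n_responses = 2, levels = paste0("L", 1:4), n = 15)`.
#' @param path Output path (`.xlsx`).
#' @param scenario `"S3"` (one sheet) or `"S4"` (multiple).
#' @param dispersion_kind Write SDs or SEMs (default `"SEM"`).
#' @inheritParams make_raw_workbook
#' @return Invisibly, list with `path`, `truth_path`, `truth`.
#' @export
make_summary_workbook <- function(config, path, scenario = c("S3", "S4"),
                                  dispersion_kind = c("SEM", "SD"),
                                  start_row = 1L, start_col = 1L) {
  scenario <- match.arg(scenario)
  dispersion_kind <- match.arg(dispersion_kind)
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  n_sheets <- if (scenario == "S3") 1L else config$n_sheets
  sheets <- list()
  truth <- list()
  for (s in seq_len(n_sheets)) {
    fac <- rep(config$levels, times = config$n)
    df <- data.frame(Group = config$levels, stringsAsFactors = FALSE)
    for (v in seq_len(config$n_responses)) {
      y <- rep(config$group_effects, times = config$n) +
        stats::rnorm(sum(config$n), 0, config$sigma)
      vn <- paste0("Var", v)
      m <- vapply(config$levels, function(g) mean(y[fac == g]), numeric(1))
      sd_g <- vapply(config$levels, function(g) stats::sd(y[fac == g]),
                     numeric(1))
      disp <- if (dispersion_kind == "SD") sd_g else sd_g / sqrt(config$n)
      df[[vn]] <- unname(m)
      df[[paste0(vn, "_", dispersion_kind)]] <- unname(disp)
      truth[[length(truth) + 1L]] <- data.frame(
        sheet = sheet_name(s, n_sheets), response = vn,
        label = config$levels, n = config$n,
        true_mean = config$group_effects, true_sd = config$sigma,
        sample_mean = unname(m), sample_sd = unname(sd_g),
        stringsAsFactors = FALSE)
    }
    sheets[[sheet_name(s, n_sheets)]] <- df
  }
  write_xlsx(sheets, path, start_row = start_row, start_col = start_col)
  truth <- do.call(rbind, truth)
  truth_path <- paste0(path, ".truth.tsv")
  write_truth(truth, truth_path)
  invisible(list(path = path, truth_path = truth_path, truth = truth))
}

sheet_name <- function(s, n_sheets) {
  if (n_sheets == 1L) "Data" else paste0("Data", s)
}

write_truth <- function(truth, path) {
  utils::write.table(format(truth, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Reference summary dataset: IFNT dose response in ZDF rat plasma
#'
#' The packaged 11-response summary dataset used throughout the package's
#' tests and examples: plasma metabolite and hormone concentrations of
#' Zucker diabetic fatty rats under oral interferon tau at doses 0, 4, and
#' 8 ug/kg body weight per day, summarized as mean ± SEM with n = 6 per
#' group. Alongside each response the published letter partition is
#' recorded (as a partition, i.e. up to letter renaming): nine responses
#' separate the two lower doses from the high dose; insulin and adiponectin
#' show no significant differences and carry a single class.
#'
#' @return List with elements `summaries` (list of 11 [response_summary()]
#'   objects), `partitions` (named list of published letter partitions, one
#'   per response), `units` (named character vector), and `doses` (group
#'   labels `"0"`, `"4"`, `"8"`).
#' @examples
#' t1 <- table1_data()
#' anova_from_summary(t1$summaries[["Arginine"]])
#' @export
table1_data <- function() {
  doses <- c("0", "4", "8")
  spec <- list(
    #            means                SEMs               mean sem digits
    Arginine     = list(c(110, 115, 149),    c(4, 5, 6),          0L, 0L, "uM"),
    Valine       = list(c(219, 201, 172),    c(9, 7, 6),          0L, 0L, "uM"),
    Isoleucine   = list(c(208, 206, 178),    c(8, 7, 6),          0L, 0L, "uM"),
    Leucine      = list(c(245, 233, 196),    c(10, 9, 8),         0L, 0L, "uM"),
    Glucose      = list(c(24.5, 23.8, 21.9), c(0.3, 0.4, 0.4),    1L, 1L, "mM"),
    FFA          = list(c(1.60, 1.53, 1.34), c(0.06, 0.05, 0.05), 2L, 2L, "mM"),
    TAG          = list(c(6.05, 5.90, 5.17), c(0.13, 0.27, 0.11), 2L, 2L, "mM"),
    Cholesterol  = list(c(5.18, 4.94, 4.23), c(0.23, 0.24, 0.13), 2L, 2L, "mM"),
    Insulin      = list(c(307, 294, 301),    c(10, 11, 7),        0L, 0L, "pM"),
    Adiponectin  = list(c(2.78, 2.94, 2.64), c(0.08, 0.09, 0.13), 2L, 2L, "mg/L"),
    Leptin       = list(c(19.6, 19.3, 13.7), c(1.2, 1.0, 0.9),    1L, 1L, "ug/L")
  )
  summaries <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    response_summary(nm, doses, n = 6L, mean = s[[1]], dispersion = s[[2]],
                     dispersion_kind = "SEM", digits = s[[3]],
                     sem_digits = s[[4]])
  })
  names(summaries) <- names(spec)
  single <- list(doses)                       # one class: no letters
  split_high <- list(c("0", "4"), "8")        # low doses vs high dose
  partitions <- lapply(names(spec), function(nm) {
    if (nm %in% c("Insulin", "Adiponectin")) single else split_high
  })
  names(partitions) <- names(spec)
  units <- vapply(spec, function(s) s[[5]], "")
  list(summaries = summaries, partitions = partitions,
       units = units, doses = doses)
}
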