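#' Per-group summary statistics for one response variable
#'
#' A `response_summary` is the package's central exchange object: every input
#' path (raw observations, summary spreadsheets, the packaged reference
#' dataset) is reduced to one of these before analysis, so the ANOVA and all
#' post-hoc procedures have a single computation path.
#'
#' Dispersion may be given either as the group standard deviation (SD) or as
#' the standard error of the mean (SEM = SD/sqrt(n)); the SD is derived
#' internally as `SEM * sqrt(n)` and all computation uses the SD. Display
#' precision (`digits`, `sem_digits`) records how many decimal places the
#' source printed, so rendered tables can echo the source's precision;
#' it never affects computation.
#'
#' @param variable Response variable name (single string).
#' @param labels Group labels, one per group, unique, in presentation order.
#' @param n Per-group sample sizes (each >= 2); a single value is recycled.
#' @param mean Per-group means.
#' @param dispersion Per-group nonnegative dispersion values.
#' @param dispersion_kind Either `"SD"` or `"SEM"`, one value for the whole
#'   response.
#' @param digits Decimal places for displaying the means (single value or one
#'   per group); if `NULL`, inferred from the values supplied.
#' @param sem_digits Decimal places for displaying the SEMs; if `NULL`,
#'   inferred like `digits`.
#' @return An object of class `response_summary`: a list with elements
#'   `variable` (string) and `groups` (data frame with columns `label`, `n`,
#'   `mean`, `dispersion`, `dispersion_kind`, `sd`, `sem`, `digits`,
#'   `sem_digits`).
#' @examples
#' response_summary("Arginine", c("0", "4", "8"), n = 6,
#'                  mean = c(110, 115, 149), dispersion = c(4, 5, 6),
#'                  dispersion_kind = "SEM")
#' @export
response_summary <- function(variable, labels, n, mean, dispersion,
                             dispersion_kind = c("SD", "SEM"),
                             digits = NULL, sem_digits = NULL) {
  dispersion_kind <- match.arg(dispersion_kind)
  stopifnot(is.character(variable), length(variable) == 1L)
  labels <- as.character(labels)
  k <- length(labels)
  if (k < 2L) stop("factor must have >=2 levels (got ", k, ")")
  if (anyDuplicated(labels))
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- rep_len(as.numeric(n), k)
  mean <- as.numeric(mean)
  dispersion <- as.numeric(dispersion)
  if (length(dispersion) == 1L) dispersion <- rep_len(dispersion, k)
  if (length(mean) != k || length(dispersion) != k)
    stop("labels, mean and dispersion must have one entry per group")
  if (anyNA(n) || anyNA(mean) || anyNA(dispersion))
    stop("missing values are not allowed in summary input")
  if (any(n < 2)) stop("group too small: every group needs n >= 2")
  if (any(n != round(n))) stop("sample sizes must be whole numbers")
  if (any(dispersion < 0)) stop("dispersion must be nonnegative")
  sd <- if (dispersion_kind == "SD") dispersion else dispersion * sqrt(n)
  sem <- sd / sqrt(n)
  if (is.null(digits)) digits <- max(infer_digits(mean))
  if (is.null(sem_digits)) sem_digits <- max(infer_digits(dispersion))
  groups <- data.frame(
    label = labels, n = n, mean = mean,
    dispersion = dispersion, dispersion_kind = dispersion_kind,
    sd = sd, sem = sem,
    digits = rep_len(as.integer(digits), k),
    sem_digits = rep_len(as.integer(sem_digits), k),
    stringsAsFactors = FALSE
  )
  structure(list(variable = variable, groups = groups),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat("Response summary:", x$variable, "\n")
  print(x$groups[, c("label", "n", "mean", "sd", "sem")], row.names = FALSE)
  invisible(x)
}

# Decimal places needed to print x exactly (capped at 6); used to echo the
# source's display precision when none is recorded.
infer_digits <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(0L)
    for (d in 0:6) if (abs(v - round(v, d)) < 1e-9 * max(1, abs(v))) return(d)
    6L
  }, integer(1))
}

#' Reduce raw factor/response observations to per-group summaries
#'
#' Rows where either the factor label or the response value is missing are
#' dropped; missingness is marked by `NA` or an empty string. Group order is
#' first appearance in the input. Dispersion is the sample SD (n-1
#' denominator).
#'
#' @param factor_values Group labels (character or factor; `NA`/empty =
#'   missing).
#' @param response_values Numeric responses, same length (`NA` = missing).
#'   Character vectors are parsed; a non-numeric, non-missing token is an
#'   error naming the offending row.
#' @param variable Name recorded for the response (default `"response"`).
#' @param digits Display precision passed through to [response_summary()]
#'   (default 2, the usual choice for measured quantities).
#' @return A [response_summary()].
#' @examples
#' summarize_raw(c("A", "A", "A", "B", "B", "B"), c(1, 2, 3, 2, 3, 4))
#' @export
summarize_raw <- function(factor_values, response_values,
                          variable = "response", digits = 2L) {
  if (length(factor_values) != length(response_values))
    stop("factor and response must have the same length")
  fac <- as.character(factor_values)
  fac[!is.na(fac) & !nzchar(trimws(fac))] <- NA_character_
  y <- parse_numeric(response_values, variable)
  keep <- !is.na(fac) & !is.na(y)
  fac <- fac[keep]; y <- y[keep]
  lev <- unique(fac)
  if (length(lev) < 2L)
    stop("factor must have >=2 levels after removing missing rows")
  n <- vapply(lev, function(g) sum(fac == g), numeric(1))
  if (any(n < 2))
    stop("group too small: ", paste(lev[n < 2], collapse = ", "),
         " (every group needs n >= 2 non-missing observations)")
  m <- vapply(lev, function(g) mean(y[fac == g]), numeric(1))
  s <- vapply(lev, function(g) stats::sd(y[fac == g]), numeric(1))
  response_summary(variable, lev, n, m, s, dispersion_kind = "SD",
                   digits = digits, sem_digits = digits)
}

# Numeric parse that treats NA/"" as missing and reports the position of
# anything else that fails to parse.
parse_numeric <- function(x, variable = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  y <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(y))
  if (length(bad))
    stop("non-numeric value in '", variable, "' at row ", bad[1],
         ": \"", x[bad[1]], "\"")
  y
}
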