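#' Read an analysis workbook (raw or summary data)
#'
#' Reads one of the four supported input arrangements:
#'
#' * `S1` — a single raw dataset in one sheet: one factor column plus one or
#'   more numeric response columns, rows = experimental units.
#' * `S2` — multiple raw datasets, one per sheet, in one workbook.
#' * `S3` — a single summary dataset: one row per group, first column the
#'   group label, then for each response a mean column (whose header names
#'   the response) immediately followed by its dispersion (SD or SEM)
#'   column.
#' * `S4` — multiple summary datasets, one per sheet.
#'
#' XLSX and XLS are read through readxl; CSV (single sheet, so `S1`/`S3`
#' only) through base R, with empty fields or `NA` as missing. The data
#' rectangle need not be anchored at the top-left cell: the reader locates
#' the single contiguous block of non-empty cells and takes its first row as
#' the header (two disjoint blocks in one sheet is an error, not a guess).
#' Column names are case-sensitive.
#'
#' Summary scenarios require the per-group sample sizes, which published
#' tables rarely carry, via `sizes_spec` (see [parse_sizes()]), and a
#' declaration of whether the dispersion columns hold SDs or SEMs.
#'
#' @param path File path (`.xlsx`, `.xls`, or `.csv`).
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param factor_name Name of the factor column (raw scenarios; required).
#' @param dispersion_kind `"SEM"` (default) or `"SD"` (summary scenarios).
#' @param sizes_spec Sample-size specification string (summary scenarios),
#'   e.g. `"15"` or `"15 14 15 16"`.
#' @param raw_digits Display precision for raw-data tables (default 2).
#' @return An object of class `workbook`: list with `path`, `scenario`, and
#'   `sheets`, a list of dataset bundles. Each bundle has `name`, `mode`
#'   (`"raw"` or `"summary"`), and either `factor_name` + `data` (raw) or
#'   `summaries`, a list of [response_summary()] objects.
#' @export
read_workbook <- function(path, scenario = c("S1", "S2", "S3", "S4"),
                          factor_name = NULL,
                          dispersion_kind = c("SEM", "SD"),
                          sizes_spec = NULL, raw_digits = 2L) {
  scenario <- match.arg(scenario)
  dispersion_kind <- match.arg(dispersion_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw_mode <- scenario %in% c("S1", "S2")
  multi <- scenario %in% c("S2", "S4")
  if (ext %in% c("xlsx", "xls")) {
    sheet_names <- readxl::excel_sheets(path)
    if (!multi) sheet_names <- sheet_names[1]
    cells <- lapply(sheet_names, function(s) read_cells_xlsx(path, s))
    names(cells) <- sheet_names
  } else if (ext == "csv") {
    if (multi)
      stop("CSV has a single sheet; scenarios S2/S4 need an xlsx/xls workbook")
    cells <- list(read_cells_csv(path))
    names(cells) <- tools::file_path_sans_ext(basename(path))
  } else {
    stop("unsupported file extension '.", ext, "' (use .xlsx, .xls or .csv)")
  }
  bundles <- lapply(names(cells), function(nm) {
    tab <- locate_region(cells[[nm]], sheet = nm)
    if (raw_mode) {
      bundle_raw(tab, nm, factor_name, raw_digits)
    } else {
      bundle_summary(tab, nm, dispersion_kind, sizes_spec)
    }
  })
  names(bundles) <- names(cells)
  structure(list(path = path, scenario = scenario, sheets = bundles),
            class = "workbook")
}

# Full sheet as a character matrix (numbers in their text form, NA = empty).
read_cells_xlsx <- function(path, sheet) {
  df <- suppressMessages(readxl::read_excel(
    path, sheet = sheet, col_names = FALSE, col_types = "text",
    .name_repair = "minimal"))
  if (nrow(df) == 0L || ncol(df) == 0L) return(matrix(NA_character_, 0, 0))
  as.matrix(as.data.frame(df, stringsAsFactors = FALSE))
}

read_cells_csv <- function(path) {
  df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                        na.strings = c("", "NA"), check.names = FALSE,
                        blank.lines.skip = FALSE)
  as.matrix(df)
}

# Locate the single contiguous rectangular data block; header = first row.
locate_region <- function(cells, sheet = "") {
  if (length(cells) == 0L) stop("sheet '", sheet, "' is empty")
  filled <- !is.na(cells) & nzchar(trimws(cells))
  if (!any(filled)) stop("sheet '", sheet, "' is empty")
  row_any <- apply(filled, 1, any)
  col_any <- apply(filled, 2, any)
  if (n_runs(row_any) > 1L || n_runs(col_any) > 1L)
    stop("sheet '", sheet, "' contains more than one disjoint data block; ",
         "keep a single rectangular table per sheet")
  rows <- range(which(row_any)); cols <- range(which(col_any))
  block <- cells[seq(rows[1], rows[2]), seq(cols[1], cols[2]), drop = FALSE]
  dimnames(block) <- NULL
  header <- trimws(block[1, ])
  empty_hdr <- which(is.na(header) | !nzchar(header))
  if (length(empty_hdr))
    stop("sheet '", sheet, "': empty header cell at ",
         cell_ref(rows[1], cols[1] + empty_hdr[1] - 1),
         "; the table's first row must name every column")
  body <- block[-1, , drop = FALSE]
  list(header = header, body = body,
       origin = c(row = rows[1], col = cols[1]), sheet = sheet)
}

n_runs <- function(flag) {
  r <- rle(flag)
  sum(r$values)
}

cell_ref <- function(row, col) paste0(col_letter(col), row)

bundle_raw <- function(tab, name, factor_name, raw_digits) {
  if (is.null(factor_name))
    stop("raw scenarios need factor_name; available columns: ",
         paste(tab$header, collapse = ", "))
  idx <- which(tab$header == factor_name)
  if (length(idx) != 1L)
    stop("factor column '", factor_name, "' not found in sheet '", tab$sheet,
         "' (names are case-sensitive); available columns: ",
         paste(tab$header, collapse = ", "))
  responses <- tab$header[-idx]
  if (length(responses) < 1L)
    stop("sheet '", tab$sheet,
         "' needs at least one response column besides the factor")
  validate_names(responses)
  data <- as.data.frame(tab$body, stringsAsFactors = FALSE)
  names(data) <- tab$header
  structure(list(name = name, mode = "raw", factor_name = factor_name,
                 responses = responses, data = data,
                 raw_digits = raw_digits),
            class = "dataset_bundle")
}

bundle_summary <- function(tab, name, dispersion_kind, sizes_spec) {
  nc <- length(tab$header)
  if (nc < 3L || (nc - 1L) %% 2L != 0L)
    stop("sheet '", tab$sheet, "': a summary table needs a group-label ",
         "column followed by (mean, dispersion) column pairs; got ", nc,
         " columns")
  labels <- trimws(tab$body[, 1])
  if (any(is.na(labels) | !nzchar(labels)))
    stop("sheet '", tab$sheet, "': missing group label in the first column")
  if (is.null(sizes_spec))
    stop("summary scenarios need sizes_spec (per-group sample sizes); ",
         "e.g. \"15\" for a balanced design or \"15 14 15 16\"")
  sizes <- parse_sizes(sizes_spec, length(labels))
  resp_cols <- seq(2L, nc, by = 2L)
  resp_names <- tab$header[resp_cols]
  validate_names(resp_names)
  summaries <- lapply(seq_along(resp_cols), function(i) {
    mcol <- resp_cols[i]
    mtxt <- tab$body[, mcol]
    dtxt <- tab$body[, mcol + 1L]
    m <- parse_numeric(mtxt, tab$header[mcol])
    d <- parse_numeric(dtxt, tab$header[mcol + 1L])
    if (anyNA(m) || anyNA(d))
      stop("sheet '", tab$sheet, "': missing mean or dispersion for response '",
           resp_names[i], "'")
    response_summary(resp_names[i], labels, sizes, m, d,
                     dispersion_kind = dispersion_kind,
                     digits = max(text_decimals(mtxt)),
                     sem_digits = max(text_decimals(dtxt)))
  })
  structure(list(name = name, mode = "summary", responses = resp_names,
                 summaries = summaries, sizes = sizes),
            class = "dataset_bundle")
}

# Decimal places as printed in the source text, e.g. "1.60" -> 2.
text_decimals <- function(x) {
  x <- as.character(x)
  vapply(x, function(v) {
    if (is.na(v)) return(0L)
    v <- trimws(v)
    dot <- regexpr(".", v, fixed = TRUE)
    if (dot < 0) 0L else nchar(v) - dot
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse a per-group sample-size specification
#'
#' A single token is the common size of a balanced design and is replicated
#' for every group; otherwise exactly one whitespace-separated token per
#' group is required, assigned in the order the groups appear in the source
#' table. Every size must be a whole number of at least 2.
#'
#' @param spec Character scalar, e.g. `"15"` or `"15 14 15 16"`.
#' @param n_groups Number of groups in the dataset.
#' @return Integer vector of length `n_groups`.
#' @examples
#' parse_sizes("15", 4)           # 15 15 15 15
#' parse_sizes("15 14 15 16", 4)  # 15 14 15 16
#' @export
parse_sizes <- function(spec, n_groups) {
  stopifnot(length(spec) == 1L, n_groups >= 2L)
  tokens <- strsplit(trimws(as.character(spec)), "\\s+")[[1]]
  if (length(tokens) == 0L || !nzchar(spec))
    stop("empty sample-size specification")
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals) || any(vals != round(vals)))
    stop("sample sizes must be whole numbers; got \"", spec, "\"")
  if (any(vals < 2))
    stop("every group needs a sample size of at least 2")
  if (length(vals) == 1L) return(rep.int(as.integer(vals), n_groups))
  if (length(vals) != n_groups)
    stop("expected 1 or ", n_groups, " sample sizes, got ", length(vals))
  as.integer(vals)
}

#' Validate variable names
#'
#' Names containing spaces are rejected outright (they break downstream
#' model syntax and column lookup), duplicated names are rejected, and names
#' longer than 10 characters draw a warning recommending a descriptive
#' abbreviation — long names survive unchanged; nothing is silently
#' truncated.
#'
#' @param names Character vector of variable names.
#' @return Invisibly, a data frame with columns `name`, `sanitized_name`
#'   (always equal to `name`), and `warnings`.
#' @export
validate_names <- function(names) {
  names <- as.character(names)
  spaced <- grepl("\\s", names)
  if (any(spaced))
    stop("space in variable name: \"", names[which(spaced)[1]],
         "\"; rename the column without spaces (e.g. Total_cholesterol)")
  if (anyDuplicated(names))
    stop("duplicate variable names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  warn <- ifelse(nchar(names) > 10L,
                 "name exceeds 10 characters; consider a descriptive abbreviation",
                 "")
  for (nm in names[nchar(names) > 10L])
    warning("variable name '", nm, "' exceeds 10 characters; ",
            "consider a descriptive abbreviation", call. = FALSE)
  invisible(data.frame(name = names, sanitized_name = names,
                       warnings = warn, stringsAsFactors = FALSE))
}

#' @export
print.workbook <- function(x, ...) {
  cat("Workbook:", x$path, "(", x$scenario, ")\n")
  for (b in x$sheets)
    cat(sprintf("  sheet '%s': %s mode, responses: %s\n", b$name, b$mode,
                paste(b$responses, collapse = ", ")))
  invisible(x)
}
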