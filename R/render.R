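#' Assemble a publication table from per-response analysis results
#'
#' Builds the renderable table in one of the two formats common in
#' life-science journals:
#'
#' * `per_group_sem` — each cell shows "mean ± SEM" with superscript
#'   letters from the compact letter display.
#' * `pooled_sem` — cells show the mean only, with one extra column
#'   carrying the pooled SEM (sqrt(MSE/n)) per response row.
#'
#' Rows whose letter display has a single class (no pair significantly
#' different) carry no superscripts. Means and SEMs are printed at the
#' display precision recorded in each [response_summary()]; the pooled SEM
#' uses one decimal more than the means, since it is typically an order of
#' magnitude smaller. The footnote states the significance convention, the
#' level, and the test used.
#'
#' @param results List, one element per response, each a list with elements
#'   `summary` ([response_summary()]), `anova`, `mcp`, and `cld`; the output
#'   of [analyze_response()].
#' @param mode `"per_group_sem"` or `"pooled_sem"`.
#' @param alpha Significance level for the footnote.
#' @param test_name Test label for the footnote (e.g. `"SNK"`).
#' @param title Table title (default a generic one).
#' @return An object of class `table_spec`: list with `title`,
#'   `group_headers`, `rows` (each: `variable`, `cells`, `letters`,
#'   `pooled_sem`), `mode`, `alpha`, `footnote`.
#' @export
build_table <- function(results, mode = c("per_group_sem", "pooled_sem"),
                        alpha = 0.05, test_name = "",
                        title = "One-way ANOVA results") {
  mode <- match.arg(mode)
  if (length(results) == 0L) stop("nothing to render: no analysis results")
  labels <- results[[1]]$summary$groups$label
  rows <- lapply(results, function(res) {
    g <- res$summary$groups
    if (!identical(g$label, labels))
      stop("inconsistent group labels across responses: response '",
           res$summary$variable, "' has ",
           paste(g$label, collapse = "/"), " but the first response has ",
           paste(labels, collapse = "/"))
    letters_row <- res$cld$letters
    if (length(res$cld$partition) < 2L) letters_row <- rep("", nrow(g))
    cells <- if (mode == "per_group_sem") {
      paste0(format_value(g$mean, g$digits), " ± ",
             format_value(g$sem, g$sem_digits))
    } else {
      format_value(g$mean, g$digits)
    }
    list(variable = res$summary$variable,
         cells = cells,
         letters = letters_row,
         pooled_sem = if (mode == "pooled_sem")
           format_value(res$anova$pooled_sem, max(g$digits) + 1L)
         else NULL)
  })
  note_mode <- if (mode == "per_group_sem")
    "Values are the means ± SEM." else "Values are the means."
  footnote <- sprintf(
    "%s Means in a row without a common superscript letter differ (P < %s), as analyzed by one-way ANOVA%s.",
    note_mode, format(alpha),
    if (nzchar(test_name)) paste0(" with the ", test_name, " test") else "")
  structure(list(title = title, group_headers = labels, rows = rows,
                 mode = mode, alpha = alpha, footnote = footnote),
            class = "table_spec")
}

#' Fixed-point display formatting
#'
#' Formats numbers at a fixed number of decimal places with ties rounded
#' half away from zero (the convention of published tables), rather than the
#' round-half-even rule of [round()].
#'
#' @param value Numeric vector.
#' @param precision Decimal places (>= 0), recycled along `value`.
#' @return Character vector.
#' @examples
#' format_value(c(110, 1.6, 5.066), c(0, 2, 1))  # "110" "1.60" "5.1"
#' @export
format_value <- function(value, precision) {
  precision <- rep_len(as.integer(precision), length(value))
  if (any(precision < 0)) stop("precision must be >= 0")
  vapply(seq_along(value), function(i) {
    p <- 10^precision[i]
    # tiny nudge keeps values stored just under a half-tie (5.065999...)
    # rounding the way their printed form implies
    v <- sign(value[i]) * floor(abs(value[i]) * p + 0.5 + 1e-9) / p
    sprintf("%.*f", precision[i], v)
  }, "")
}

#' Write a table as an RTF document
#'
#' Produces a single-table RTF 1.x file: bold title and header row, one
#' table row per response, superscript letters via the `\super` control
#' word, "±" as the `\'b1` code-page escape, and the footnote as a trailing
#' paragraph. Output is a pure function of the `table_spec`, so identical
#' input yields a byte-identical file. The document opens in Microsoft Word
#' and other RTF readers.
#'
#' @param table A `table_spec` from [build_table()].
#' @param path Output path (`.rtf`).
#' @return `path`, invisibly.
#' @export
write_rtf <- function(table, path) {
  stopifnot(inherits(table, "table_spec"))
  if (length(table$rows) == 0L) stop("nothing to render: empty rows list")
  ncell <- 1L + length(table$group_headers) +
    as.integer(table$mode == "pooled_sem")
  right_edges <- 2800 + 1700 * seq_len(ncell - 1L)
  right_edges <- c(2800, right_edges)[seq_len(ncell)]
  row_prefix <- paste0("\\trowd\\trgaph108",
                       paste0("\\cellx", right_edges, collapse = ""))
  cell <- function(txt) paste0("\\intbl ", txt, "\\cell")
  header_cells <- c("", table$group_headers,
                    if (table$mode == "pooled_sem") "Pooled SEM")
  header <- paste0(row_prefix,
                   paste0(cell(paste0("{\\b ", rtf_escape(header_cells), "}")),
                          collapse = ""),
                   "\\row")
  body <- vapply(table$rows, function(r) {
    cells <- paste0(rtf_escape(r$cells),
                    ifelse(nzchar(r$letters),
                           paste0("{\\super ", rtf_escape(r$letters), "}"), ""))
    cells <- c(rtf_escape(r$variable), cells,
               if (!is.null(r$pooled_sem)) rtf_escape(r$pooled_sem))
    paste0(row_prefix, paste0(cell(cells), collapse = ""), "\\row")
  }, "")
  doc <- paste0(
    "{\\rtf1\\ansi\\ansicpg1252\\deff0\n",
    "{\\fonttbl{\\f0\\froman Times New Roman;}}\n",
    "\\f0\\fs20\n",
    "{\\pard\\b ", rtf_escape(table$title), "\\par}\n",
    paste0(header, "\n"),
    paste0(body, collapse = "\n"), "\n",
    "{\\pard ", rtf_escape(table$footnote), "\\par}\n",
    "}\n")
  writeChar(doc, path, eos = NULL, useBytes = TRUE)
  invisible(path)
}

# RTF uses ASCII with escapes; non-ASCII goes out as code-page escapes
# (for the characters this package emits, that is "±" -> \'b1).
rtf_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("{", "\\{", x, fixed = TRUE)
  x <- gsub("}", "\\}", x, fixed = TRUE)
  x <- gsub("±", "\\'b1", x, fixed = TRUE)
  vapply(x, function(s) {
    if (!any(utf8ToInt(s) > 127)) return(s)
    ints <- utf8ToInt(s)
    paste0(ifelse(ints > 127, sprintf("\\u%d?", ints), intToUtf8(ints, multiple = TRUE)),
           collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Recover cell texts from an RTF table
#'
#' A minimal reader for the documents produced by [write_rtf()], used to
#' verify the writer by round trip. It tokenizes control words, groups, and
#' code-page escapes, concatenates the visible text of each table cell
#' (superscript content is appended directly after the base text), and
#' splits on `\cell` / `\row`.
#'
#' @param path An RTF file.
#' @return List of character vectors, one per table row.
#' @export
read_rtf_cells <- function(path) {
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  buf <- character(0)
  rows <- list(); cells <- character(0)
  flush_cell <- function() {
    cells[[length(cells) + 1L]] <<- trimws(paste0(buf, collapse = ""))
    buf <<- character(0)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\") {
      nxt <- if (i < n) chars[i + 1L] else ""
      if (nxt == "'") {
        hex <- paste0(chars[i + 2L], chars[i + 3L])
        code <- strtoi(hex, 16L)
        buf <- c(buf, intToUtf8(code))
        i <- i + 4L
      } else if (nxt %in% c("\\", "{", "}")) {
        buf <- c(buf, nxt)
        i <- i + 2L
      } else {
        j <- i + 1L
        while (j <= n && grepl("[a-zA-Z]", chars[j])) j <- j + 1L
        word <- paste0(chars[seq(i + 1L, j - 1L)], collapse = "")
        while (j <= n && grepl("[-0-9]", chars[j])) j <- j + 1L
        param_end <- j
        if (j <= n && chars[j] == " ") j <- j + 1L  # delimiter space
        if (word %in% c("trowd", "pard", "par")) {
          # text before the next cell (titles, font names) is not cell content
          buf <- character(0)
        } else if (word == "u") {
          # \uN? unicode escape: emit the code point, skip fallback "?"
          num <- suppressWarnings(as.integer(paste0(
            chars[seq(i + 2L, param_end - 1L)], collapse = "")))
          if (!is.na(num)) buf <- c(buf, intToUtf8(num))
          if (j <= n && chars[j] == "?") j <- j + 1L
        } else if (word == "cell") {
          flush_cell()
        } else if (word == "row") {
          if (length(cells)) rows[[length(rows) + 1L]] <- unlist(cells)
          cells <- character(0)
        }
        i <- j
      }
    } else if (ch %in% c("{", "}", "\n", "\r")) {
      i <- i + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  rows
}

#' Write a table as TSV or Markdown
#'
#' Flat plain-text mirrors of the RTF output for inspection and diffing;
#' superscript letters become plain suffixes separated by a space
#' (`"110 ± 4 b"`).
#'
#' @param table A `table_spec` from [build_table()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_text <- function(table, path, dialect = c("tsv", "markdown")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "table_spec"))
  if (length(table$rows) == 0L) stop("nothing to render: empty rows list")
  header <- c("Variable", table$group_headers,
              if (table$mode == "pooled_sem") "Pooled SEM")
  lines_body <- vapply(table$rows, function(r) {
    cells <- paste0(r$cells, ifelse(nzchar(r$letters),
                                    paste0(" ", r$letters), ""))
    row <- c(r$variable, cells,
             if (!is.null(r$pooled_sem)) r$pooled_sem)
    if (dialect == "tsv") paste(row, collapse = "\t")
    else paste0("| ", paste(row, collapse = " | "), " |")
  }, "")
  out <- if (dialect == "tsv") {
    c(paste(header, collapse = "\t"), lines_body, "", table$footnote)
  } else {
    c(paste0("| ", paste(header, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
      lines_body, "", table$footnote)
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.table_spec <- function(x, ...) {
  cat(x$title, "\n")
  hdr <- c("Variable", x$group_headers,
           if (x$mode == "pooled_sem") "Pooled SEM")
  cat(paste(hdr, collapse = " | "), "\n")
  for (r in x$rows) {
    cells <- paste0(r$cells, ifelse(nzchar(r$letters),
                                    paste0(" ", r$letters), ""))
    cat(paste(c(r$variable, cells, r$pooled_sem), collapse = " | "), "\n")
  }
  cat(x$footnote, "\n")
  invisible(x)
}
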