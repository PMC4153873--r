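#' Minimal deterministic XLSX writer
#'
#' Writes a list of data frames as an Office Open XML spreadsheet: one
#' worksheet per data frame, header row from column names, numbers as
#' numeric cells and everything else as inline strings, `NA` as empty cells.
#' The container is an uncompressed (stored) ZIP with fixed timestamps, so
#' identical input always yields a byte-identical file — a property the
#' synthetic-workbook fixtures rely on. The writer covers exactly what this
#' package's readers need (values only: no styles, shared strings, formulas
#' or dates) and is not a general spreadsheet library.
#'
#' @param sheets Named list of data frames; names become sheet names.
#' @param path Output path (`.xlsx`).
#' @param start_row,start_col 1-based position of the header cell, letting
#'   fixtures exercise tables not anchored at A1.
#' @return `path`, invisibly.
#' @export
write_xlsx <- function(sheets, path, start_row = 1L, start_col = 1L) {
  if (is.data.frame(sheets)) sheets <- list(Sheet1 = sheets)
  stopifnot(is.list(sheets), length(sheets) >= 1L)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets))))
    stop("every sheet needs a name")
  stopifnot(start_row >= 1L, start_col >= 1L)
  n <- length(sheets)
  ct <- paste0(
    xml_decl(),
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste0(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                   seq_len(n)), collapse = ""),
    '</Types>')
  rels <- paste0(
    xml_decl(),
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
  wb <- paste0(
    xml_decl(),
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"',
    ' xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste0(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                   xml_escape(names(sheets)), seq_len(n), seq_len(n)),
           collapse = ""),
    '</sheets></workbook>')
  wbrels <- paste0(
    xml_decl(),
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste0(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                   seq_len(n), seq_len(n)), collapse = ""),
    '</Relationships>')
  entries <- list(
    "[Content_Types].xml" = charToRaw(ct),
    "_rels/.rels" = charToRaw(rels),
    "xl/workbook.xml" = charToRaw(wb),
    "xl/_rels/workbook.xml.rels" = charToRaw(wbrels))
  for (i in seq_len(n))
    entries[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(worksheet_xml(sheets[[i]], start_row, start_col))
  zip_store(entries, path)
  invisible(path)
}

xml_decl <- function() '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n'

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Spreadsheet column name: 1 -> A, 27 -> AA, ...
col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

worksheet_xml <- function(df, start_row, start_col) {
  stopifnot(is.data.frame(df))
  row_xml <- function(vals, rowno) {
    cells <- character(0)
    for (jj in seq_along(vals)) {
      v <- vals[[jj]]
      if (length(v) != 1L || is.na(v)) next
      if (is.character(v) && !nzchar(v)) next
      ref <- paste0(col_letter(start_col + jj - 1L), rowno)
      cells <- c(cells, if (is.numeric(v)) {
        sprintf('<c r="%s"><v>%s</v></c>', ref,
                formatC(v, digits = 17, format = "g"))
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
                ref, xml_escape(as.character(v)))
      })
    }
    sprintf('<row r="%d">%s</row>', rowno, paste0(cells, collapse = ""))
  }
  header <- row_xml(as.list(names(df)), start_row)
  body <- vapply(seq_len(nrow(df)), function(r)
    row_xml(as.list(df[r, , drop = FALSE]), start_row + r), "")
  paste0(xml_decl(),
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", header, paste0(body, collapse = ""),
         "</sheetData></worksheet>")
}

# --- stored-ZIP container -------------------------------------------------
# Fixed DOS timestamp (0x21 = 1980-01-01) keeps output byte-stable.

le_bytes <- function(x, size) {
  x <- as.numeric(x)
  b <- numeric(size)
  for (i in seq_len(size)) {
    b[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(b)
}

crc32_of <- function(data) {
  hex <- digest::digest(data, algo = "crc32", serialize = FALSE)
  # parse hex to double (values can exceed .Machine$integer.max)
  sum(strtoi(strsplit(hex, "")[[1]], 16L) * 16^(rev(seq_len(nchar(hex))) - 1))
}

zip_store <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  centrals <- list()
  off <- 0
  for (nm in names(entries)) {
    data <- entries[[nm]]
    fn <- charToRaw(nm)
    crc <- crc32_of(data)
    local_hdr <- c(charToRaw("PK\x03\x04"),
                   le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
                   le_bytes(0, 2), le_bytes(0x21, 2),
                   le_bytes(crc, 4), le_bytes(length(data), 4),
                   le_bytes(length(data), 4),
                   le_bytes(length(fn), 2), le_bytes(0, 2))
    writeBin(c(local_hdr, fn, data), con)
    centrals[[nm]] <- c(charToRaw("PK\x01\x02"),
                        le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2),
                        le_bytes(0, 2), le_bytes(0, 2), le_bytes(0x21, 2),
                        le_bytes(crc, 4), le_bytes(length(data), 4),
                        le_bytes(length(data), 4),
                        le_bytes(length(fn), 2), le_bytes(0, 2),
                        le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                        le_bytes(0, 4), le_bytes(off, 4), fn)
    off <- off + length(local_hdr) + length(fn) + length(data)
  }
  cd <- do.call(c, unname(centrals))
  writeBin(cd, con)
  writeBin(c(charToRaw("PK\x05\x06"),
             le_bytes(0, 2), le_bytes(0, 2),
             le_bytes(length(entries), 2), le_bytes(length(entries), 2),
             le_bytes(length(cd), 4), le_bytes(off, 4), le_bytes(0, 2)),
           con)
  invisible(path)
}
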