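# Minimal single-sheet xlsx writer (inline strings, full-precision
# numbers), sufficient for fixture generation and readable by readxl.
# Only the parts of the OOXML spreadsheet format needed for a flat
# rectangular table are emitted.

xlsx_col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    s <- paste0(LETTERS[(j - 1) %% 26 + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

xlsx_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a data frame as a minimal xlsx workbook
#'
#' One sheet, header row, numeric cells at full precision, strings as
#' inline strings, `NA` as empty cells.
#'
#' @param df Data frame.
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_minimal_xlsx <- function(df, path) {
  td <- tempfile("xlsx")
  dir.create(file.path(td, "_rels"), recursive = TRUE)
  dir.create(file.path(td, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(td, "xl", "worksheets"), recursive = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(td, "[Content_Types].xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(td, "_rels", ".rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets>',
    '</workbook>'), file.path(td, "xl", "workbook.xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(td, "xl", "_rels", "workbook.xml.rels"))
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_along(df), function(j)
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            xlsx_col_letter(j), xlsx_escape(names(df)[j])), character(1))
  rows[1L] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[[j]][i]
      if (is.na(v)) return("")
      ref <- paste0(xlsx_col_letter(j), i + 1L)
      if (is.numeric(v))
        sprintf('<c r="%s"><v>%s</v></c>', ref, formatC(v, digits = 17, format = "g"))
      else
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                xlsx_escape(as.character(v)))
    }, character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', rows, '</sheetData></worksheet>'),
    file.path(td, "xl", "worksheets", "sheet1.xml"))
  if (!dir.exists(dirname(path))) dir.create(dirname(path), recursive = TRUE)
  path <- file.path(normalizePath(dirname(path)), basename(path))
  old <- setwd(td)
  on.exit(setwd(old))
  zip::zip(path, files = c("[Content_Types].xml", "_rels/.rels",
                           "xl/workbook.xml", "xl/_rels/workbook.xml.rels",
                           "xl/worksheets/sheet1.xml"),
           mode = "mirror")
  invisible(path)
}
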