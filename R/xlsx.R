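# Minimal single-sheet OOXML (xlsx) writer: inline strings + plain numbers,
# zipped with the self-contained 'zip' package. Enough spreadsheet for
# frequency tables; read back with readxl.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.xlsx_col <- function(j) {
  # 1 -> A, 27 -> AA
  out <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

#' Write a data.frame as a single-sheet xlsx file
#'
#' Character columns become inline strings, numeric columns plain numbers;
#' the header row holds the column names.
#'
#' @param df data.frame.
#' @param path output `.xlsx` file.
#' @param sheet sheet name.
#' @return `path`, invisibly.
#' @export
write_xlsx_sheet <- function(df, path, sheet = "Sheet1") {
  stopifnot(is.data.frame(df))
  cell <- function(i, j, v) {
    ref <- paste0(.xlsx_col(j), i)
    if (is.na(v)) return(sprintf('<c r="%s"/>', ref))
    if (is.numeric(v)) {
      return(sprintf('<c r="%s"><v>%s</v></c>', ref,
                     format(v, digits = 15, scientific = FALSE)))
    }
    sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
            .xml_escape(as.character(v)))
  }
  rows <- character(nrow(df) + 1L)
  rows[1L] <- paste0('<row r="1">',
                     paste(vapply(seq_along(df), function(j) {
                       cell(1L, j, names(df)[j])
                     }, character(1)), collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    rows[i + 1L] <- paste0(sprintf('<row r="%d">', i + 1L),
                           paste(vapply(seq_along(df), function(j) {
                             cell(i + 1L, j, df[[j]][i])
                           }, character(1)), collapse = ""), "</row>")
  }
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"), file.path(tmp, "[Content_Types].xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"), file.path(tmp, "_rels", ".rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets>',
            .xml_escape(sheet)),
    "</workbook>"), file.path(tmp, "xl", "workbook.xml"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>"),
    file.path(tmp, "xl", "worksheets", "sheet1.xml"))
  old <- setwd(tmp)
  on.exit({
    setwd(old)
    unlink(tmp, recursive = TRUE)
  })
  out <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(old, path)
  zip::zip(out,
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels",
                     "xl/worksheets/sheet1.xml"),
           mode = "mirror")
  invisible(path)
}
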