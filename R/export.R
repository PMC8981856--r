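#' Export labelled distance matrices
#'
#' Writes every matrix of a named list to (a) one worksheet per matrix in a
#' single Excel XML spreadsheet (the SpreadsheetML format Excel opens
#' natively) and (b) one CSV per matrix. Values are written at full
#' precision so that re-reading reproduces them exactly.
#'
#' @param matrices Named list of square, labelled numeric matrices.
#' @param workbook_path Path of the workbook to write (`.xml`), or `NULL`
#'   to skip the workbook.
#' @param csv_dir Directory receiving one `<name>.csv` per matrix, or
#'   `NULL` to skip CSVs.
#' @return Invisibly, a character vector of the files written.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' out <- export_matrices(list(demo = m), workbook_path = tempfile(fileext = ".xml"))
export_matrices <- function(matrices, workbook_path = NULL, csv_dir = NULL) {
  if (!is.list(matrices) || !length(matrices)) {
    abort("`matrices` must be a non-empty named list of matrices")
  }
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    abort("every matrix must be named")
  }
  purrr::iwalk(matrices, function(m, nm) check_square_labelled(m, nm))
  written <- character()
  if (!is.null(workbook_path)) {
    write_workbook(matrices, workbook_path)
    written <- c(written, workbook_path)
  }
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(matrices)) {
      p <- file.path(csv_dir, paste0(nm, ".csv"))
      write_matrix_csv(matrices[[nm]], p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

write_matrix_csv <- function(m, path) {
  df <- tibble(label = rownames(m))
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a labelled matrix back from its CSV export
#' @param path CSV written by [export_matrices()].
#' @return A labelled numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# SpreadsheetML 2003 workbook: one <Worksheet> per matrix, first row and
# column carry the labels. Sheet names are truncated to Excel's 31-char cap.
write_workbook <- function(matrices, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ok <- tryCatch({
    writeLines(c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<?mso-application progid=\"Excel.Sheet\"?>",
      paste0("<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
             " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">")), con)
    for (nm in names(matrices)) {
      m <- matrices[[nm]]
      sheet <- substr(nm, 1, 31)
      writeLines(sprintf("<Worksheet ss:Name=\"%s\"><Table>", xml_escape(sheet)), con)
      hdr <- paste0("<Cell><Data ss:Type=\"String\">",
                    xml_escape(c("", colnames(m))), "</Data></Cell>", collapse = "")
      writeLines(paste0("<Row>", hdr, "</Row>"), con)
      for (i in seq_len(nrow(m))) {
        cells <- paste0("<Cell><Data ss:Type=\"Number\">", num_chr(m[i, ]),
                        "</Data></Cell>", collapse = "")
        writeLines(paste0("<Row><Cell><Data ss:Type=\"String\">",
                          xml_escape(rownames(m)[i]), "</Data></Cell>",
                          cells, "</Row>"), con)
      }
      writeLines("</Table></Worksheet>", con)
    }
    writeLines("</Workbook>", con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("could not write workbook at '%s'", path))
  invisible(path)
}

#' Read matrices back from an exported workbook
#'
#' @param path Workbook written by [export_matrices()].
#' @return Named list of labelled numeric matrices, one per worksheet.
#' @export
read_workbook_matrices <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(ss = "urn:schemas-microsoft-com:office:spreadsheet")
  sheets <- xml2::xml_find_all(doc, ".//ss:Worksheet", ns)
  out <- list()
  for (ws in sheets) {
    nm <- xml2::xml_attr(ws, "Name")
    rows <- xml2::xml_find_all(ws, ".//ss:Row", ns)
    cells <- lapply(rows, function(r) {
      xml2::xml_text(xml2::xml_find_all(r, ".//ss:Data", ns))
    })
    header <- cells[[1]][-1]
    body <- cells[-1]
    m <- matrix(NA_real_, length(body), length(header),
                dimnames = list(vapply(body, `[`, character(1), 1), header))
    for (i in seq_along(body)) m[i, ] <- as.numeric(body[[i]][-1])
    out[[nm]] <- m
  }
  out
}

# ---- run logging -----------------------------------------------------------

open_run_log <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  file.path(dir, "run.log")
}

log_line <- function(log_path, stage, event, detail = "") {
  if (is.null(log_path)) return(invisible(NULL))
  line <- sprintf("%s | %-12s | %-5s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, event, detail)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}
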