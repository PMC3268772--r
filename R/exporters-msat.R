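# Export of microsatellite genotypes as sample x marker matrices in three
# layouts (one-column diploid "a1/a2", two-column diploid, one-column
# haploid) and two file formats (CSV, single-file XML spreadsheet).
# Missing data is written as "0" ("0/0" in one-column diploid cells).

MSAT_LAYOUTS <- c("one_column_diploid", "two_column_diploid", "one_column_haploid")
MSAT_FILE_FORMATS <- c("csv", "spreadsheet")

#' The registry of microsatellite export layouts
#' @return Character vector of the three layout names.
#' @export
microsat_layouts <- function() MSAT_LAYOUTS

#' Export microsatellite genotypes as a matrix
#'
#' One row per sample (keyed by the DNA's source-sample external id),
#' columns per marker in the requested order.  The haploid layout refuses
#' data carrying second alleles.  Exports are read-only: the database is
#' not modified.
#'
#' @param db A database handle.
#' @param projects Vector of project ids or names to merge.
#' @param layout One of [microsat_layouts()].
#' @param markers Optional ordered `PRIMER` codes (default: all markers
#'   present in the selection, by short name).
#' @param samples Optional ordered row keys to restrict/order rows.
#' @param file_format `"csv"` or `"spreadsheet"` (single-file XML
#'   spreadsheet dialect); only used when writing to `file`.
#' @param file Optional output path.
#' @param sep Allele separator for the one-column diploid layout.
#' @param missing Missing-allele symbol.
#' @return The matrix as a data.frame (first column `sample`).
#' @export
export_microsats <- function(db, projects, layout, markers = NULL,
                             samples = NULL, file_format = "csv", file = NULL,
                             sep = "/", missing = "0") {
  authz(db, task = "e", action = "read")
  if (!layout %in% MSAT_LAYOUTS)
    stop_genolims(paste0("unknown layout '", layout, "' (supported: ",
                         paste(MSAT_LAYOUTS, collapse = ", "), ")"),
                  "genolims_unknown_format")
  if (!file_format %in% MSAT_FILE_FORMATS)
    stop_genolims(paste0("unknown file format '", file_format, "'"),
                  "genolims_unknown_format")
  pids <- vapply(projects, function(p) project_id_for(db, p), integer(1))
  rows <- dbGetQuery(db$con, sprintf(
    "SELECT m.dna_id, m.allele1, m.allele2, c.short_name AS marker,
            (SELECT t.external_id
               FROM dna_extraction d
               JOIN samples s ON s.sample_id = d.sample_id
               JOIN transfer t ON t.organism_id = s.organism_id
              WHERE d.dna_id = m.dna_id
              ORDER BY d.dna_extraction_id, t.transfer_id LIMIT 1) AS row_key
       FROM microsatellites m
       JOIN codes c ON c.code_id = m.primer_id
      WHERE m.project_id IN (%s)
      ORDER BY m.msat_id", paste(pids, collapse = ",")))
  if (nrow(rows) == 0L)
    stop_genolims("empty selection: no genotypes stored for these projects",
                  "genolims_empty_selection")
  rows$row_key <- ifelse(is.na(rows$row_key), as.character(rows$dna_id),
                         rows$row_key)
  if (layout == "one_column_haploid" && any(!is.na(rows$allele2)))
    stop_genolims("haploid layout requested but the selection carries diploid genotypes",
                  "genolims_layout_mismatch")

  marker_names <- if (is.null(markers)) sort(unique(rows$marker))
  else vapply(markers, function(m)
    code_short(db, code_id_for(db, "PRIMER", m)), "")
  keys <- if (is.null(samples)) unique(rows$row_key) else as.character(samples)

  km <- paste(rows$row_key, rows$marker, sep = "\r")
  out <- data.frame(sample = keys, stringsAsFactors = FALSE)
  for (mk in marker_names) {
    idx <- match(paste(keys, mk, sep = "\r"), km)
    a1 <- ifelse(is.na(idx) | is.na(rows$allele1[idx]), missing,
                 as.character(rows$allele1[idx]))
    a2 <- ifelse(is.na(idx) | is.na(rows$allele2[idx]), missing,
                 as.character(rows$allele2[idx]))
    if (layout == "two_column_diploid") {
      out[[paste0(mk, "_1")]] <- a1
      out[[paste0(mk, "_2")]] <- a2
    } else if (layout == "one_column_diploid") {
      out[[mk]] <- paste(a1, a2, sep = sep)
    } else {
      out[[mk]] <- a1
    }
  }
  rownames(out) <- NULL
  if (!is.null(file)) {
    if (file_format == "csv") write.csv(out, file, row.names = FALSE)
    else write_spreadsheet_xml(out, file)
  }
  out
}

# Minimal single-file XML spreadsheet (SpreadsheetML 2003 dialect): open,
# plain text, readable by common spreadsheet applications.
write_spreadsheet_xml <- function(df, file, sheet = "genotypes") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  row_xml <- function(vals) paste0(
    "<Row>", paste0("<Cell><Data ss:Type=\"String\">", esc(as.character(vals)),
                    "</Data></Cell>", collapse = ""), "</Row>")
  lines <- c(
    "<?xml version=\"1.0\"?>",
    paste0("<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
           " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">"),
    sprintf("<Worksheet ss:Name=\"%s\"><Table>", esc(sheet)),
    row_xml(names(df)),
    vapply(seq_len(nrow(df)), function(i) row_xml(unlist(df[i, ])), ""),
    "</Table></Worksheet></Workbook>")
  writeLines(lines, file)
  invisible(file)
}
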