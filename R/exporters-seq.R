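# Conversion of final sequence data to the seven supported formats:
# FASTA, NEXUS, PHYLIP, MEGA, MSF, PSI-BLAST and PFAM (Stockholm dialect).
# All writers are deterministic; alignment formats (everything but FASTA)
# refuse ragged sequences unless gap padding is requested.

SEQ_FORMATS <- c("fasta", "nexus", "phylip", "mega", "msf", "psi-blast", "pfam")

#' The registry of supported sequence export formats
#' @return Character vector of the seven format names.
#' @export
sequence_formats <- function() SEQ_FORMATS

# a selection is a data.frame with columns name, bases
as_selection <- function(x) {
  if (is.data.frame(x) && all(c("name", "bases") %in% names(x))) return(x)
  if (is.character(x) && !is.null(names(x)))
    return(data.frame(name = names(x), bases = unname(x), stringsAsFactors = FALSE))
  stop_genolims("selection must be a data.frame with columns name, bases",
                "genolims_invalid_value")
}

check_selection <- function(sel, format, pad) {
  if (nrow(sel) == 0L)
    stop_genolims("empty selection", "genolims_empty_selection")
  if (anyDuplicated(sel$name))
    stop_genolims("display names must be unique within a selection",
                  "genolims_duplicate_names")
  lens <- nchar(sel$bases)
  if (format != "fasta" && length(unique(lens)) > 1L) {
    if (!pad)
      stop_genolims(paste0("sequences have unequal lengths; '", format,
                           "' is an alignment format (use pad = TRUE to right-pad with '-')"),
                    "genolims_ragged")
    sel$bases <- vapply(sel$bases, function(b)
      paste0(b, strrep("-", max(lens) - nchar(b))), "", USE.NAMES = FALSE)
  }
  sel
}

write_seq_fasta <- function(sel, width = 60L) {
  unlist(lapply(seq_len(nrow(sel)), function(i)
    c(paste0(">", sel$name[[i]]), wrap_fixed(sel$bases[[i]], width))))
}

write_seq_nexus <- function(sel) {
  c("#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(sel), nchar(sel$bases[[1L]])),
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "  MATRIX",
    sprintf("  %s  %s", format(sel$name), sel$bases),
    "  ;",
    "END;")
}

# 10-character PHYLIP names: truncate, then re-suffix to keep uniqueness;
# the truncation map is attached as an attribute of the document
phylip_names <- function(names) {
  out <- substr(names, 1L, 10L)
  while (anyDuplicated(out)) {
    for (d in unique(out[duplicated(out)])) {
      idx <- which(out == d)
      for (k in seq_along(idx)) {
        suf <- paste0("_", k)
        out[idx[k]] <- paste0(substr(names[idx[k]], 1L, 10L - nchar(suf)), suf)
      }
    }
  }
  out
}

write_seq_phylip <- function(sel) {
  nm <- phylip_names(sel$name)
  doc <- c(sprintf(" %d %d", nrow(sel), nchar(sel$bases[[1L]])),
           sprintf("%-10s%s", nm, sel$bases))
  attr(doc, "truncation_map") <-
    data.frame(name = sel$name, phylip = nm, stringsAsFactors = FALSE)
  doc
}

write_seq_mega <- function(sel) {
  c("#mega",
    "!Title exported sequences;",
    "",
    unlist(lapply(seq_len(nrow(sel)), function(i)
      c(paste0("#", sel$name[[i]]), wrap_fixed(sel$bases[[i]], 60L)))))
}

# GCG checksum: sum of ((position-1) mod 57 + 1) * ascii(upper), mod 10000
gcg_checksum <- function(s) {
  codes <- utf8ToInt(toupper(s))
  sum(((seq_along(codes) - 1L) %% 57L + 1L) * codes) %% 10000L
}

write_seq_msf <- function(sel) {
  len <- nchar(sel$bases[[1L]])
  checks <- vapply(sel$bases, gcg_checksum, 0, USE.NAMES = FALSE)
  header <- c(
    sprintf(" export.msf  MSF: %d  Type: N  Check: %d ..",
            len, sum(checks) %% 10000L),
    "",
    sprintf(" Name: %s  Len: %d  Check: %d  Weight: 1.00",
            format(sel$name), len, checks),
    "",
    "//",
    "")
  starts <- seq(1L, len, by = 50L)
  blocks <- unlist(lapply(starts, function(st) {
    en <- min(st + 49L, len)
    c(sprintf("%s  %s", format(sel$name), substring(sel$bases, st, en)), "")
  }))
  c(header, blocks)
}

write_seq_psiblast <- function(sel) {
  len <- nchar(sel$bases[[1L]])
  starts <- seq(1L, len, by = 60L)
  unlist(lapply(starts, function(st) {
    en <- min(st + 59L, len)
    c(sprintf("%s %s", format(sel$name), substring(sel$bases, st, en)), "")
  }))
}

write_seq_pfam <- function(sel) {
  c("# STOCKHOLM 1.0",
    sprintf("%s %s", format(sel$name), sel$bases),
    "//")
}

#' Export a sequence selection to one of the seven supported formats
#'
#' The writer is deterministic for a fixed selection, and sequence content
#' round-trips losslessly: re-parsing the document recovers the input
#' residues.  For PHYLIP, names are truncated to 10 characters with
#' uniqueness-preserving suffixes; the map is attached as attribute
#' `truncation_map`.
#'
#' @param selection A selection from [merge_project_sequences()], a
#'   data.frame with columns `name`/`bases`, or a named character vector.
#' @param format One of [sequence_formats()].
#' @param pad Right-pad ragged sequences with `-` for alignment formats.
#' @param file Optional output path.
#' @return The document as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
export_sequences <- function(selection, format, pad = FALSE, file = NULL) {
  format <- tolower(format)
  if (!format %in% SEQ_FORMATS)
    stop_genolims(paste0("unknown format '", format, "' (supported: ",
                         paste(SEQ_FORMATS, collapse = ", "), ")"),
                  "genolims_unknown_format")
  sel <- check_selection(as_selection(selection), format, pad)
  doc <- switch(format,
    fasta = write_seq_fasta(sel),
    nexus = write_seq_nexus(sel),
    phylip = write_seq_phylip(sel),
    mega = write_seq_mega(sel),
    msf = write_seq_msf(sel),
    `psi-blast` = write_seq_psiblast(sel),
    pfam = write_seq_pfam(sel))
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Merge sequences of one marker across projects into a selection
#'
#' Collects every stored sequence of the marker over the listed projects.
#' Display names are `<project>_<sample external id>` (whitespace replaced
#' by `_`), made unique by numeric suffixing on collision.
#'
#' @param db A database handle.
#' @param marker `PRIMER` code (id or short name).
#' @param projects Vector of project ids or names.
#' @return A selection data.frame (columns `name`, `bases`, `seq_id`,
#'   `project`, `external_id`).
#' @export
merge_project_sequences <- function(db, marker, projects) {
  authz(db, task = "e", action = "read")
  marker_id <- code_id_for(db, "PRIMER", marker)
  pids <- vapply(projects, function(p) project_id_for(db, p), integer(1))
  rows <- dbGetQuery(db$con, sprintf(
    "SELECT q.seq_id, q.bases, p.name AS project,
            (SELECT t.external_id FROM transfer t
              WHERE t.organism_id = s.organism_id
              ORDER BY t.transfer_id LIMIT 1) AS external_id
       FROM sequences q
       JOIN amplified_samples a ON a.amplified_id = q.amplified_id
       JOIN dna_extraction d ON d.dna_id = a.dna_id
       JOIN samples s ON s.sample_id = d.sample_id
       JOIN projects p ON p.project_id = s.project_id
      WHERE q.primer_id = ? AND s.project_id IN (%s)
      GROUP BY q.seq_id
      ORDER BY q.seq_id", paste(pids, collapse = ",")),
    params = list(marker_id))
  if (nrow(rows) == 0L)
    stop_genolims("no sequences found for this marker/project selection",
                  "genolims_empty_selection")
  base <- gsub("\\s+", "_", paste0(rows$project, "_",
                                   ifelse(is.na(rows$external_id), rows$seq_id,
                                          rows$external_id)))
  name <- base
  if (anyDuplicated(name)) {
    for (d in unique(name[duplicated(name)])) {
      idx <- which(base == d)
      name[idx] <- paste0(d, "_", seq_along(idx))
    }
  }
  data.frame(name = name, bases = rows$bases, seq_id = rows$seq_id,
             project = rows$project, external_id = rows$external_id,
             stringsAsFactors = FALSE)
}

#' Convert an uploaded FASTA document to another format
#'
#' Stateless conversion service: parses the FASTA input (database not
#' touched) and re-emits it in any supported format.  Record names must be
#' unique.
#'
#' @param input Path of a FASTA file.
#' @param format One of [sequence_formats()].
#' @param pad Right-pad ragged sequences for alignment formats.
#' @param file Optional output path.
#' @return The converted document (character vector of lines).
#' @export
convert_fasta <- function(input, format, pad = FALSE, file = NULL) {
  set <- tryCatch(Biostrings::readBStringSet(input),
                  error = function(e)
                    stop_genolims(paste0("malformed FASTA: ", conditionMessage(e)),
                                  "genolims_bad_fasta"))
  if (length(set) == 0L)
    stop_genolims("malformed FASTA: no records", "genolims_bad_fasta")
  nm <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop_genolims("duplicate record ids in FASTA input", "genolims_duplicate_names")
  export_sequences(setNames(as.character(set), nm), format, pad = pad,
                   file = file)
}
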