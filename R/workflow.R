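# Lab workflow capture: collection, DNA extraction (with pooling),
# PCR set-up, validation, electrophoresis with raw-file blobs, and the
# import of final sequence / microsatellite data produced by external
# analysis software.  Steps pipeline into each other through spreadsheet
# templates (export_step_template -> import at the next step).

IUPAC_CHARS <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N","-",".")

assert_iupac <- function(bases, where = "sequence") {
  chars <- unique(strsplit(toupper(bases), "")[[1L]])
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad))
    stop_genolims(sprintf("%s contains non-IUPAC characters: %s", where,
                          paste(bad, collapse = " ")), "genolims_bad_sequence")
  invisible(TRUE)
}

#' Record the collection of a sample
#' @param db A database handle.
#' @param sample_id Sample.
#' @param collector_id Optional contact.
#' @param date Optional ISO date.
#' @param comment Optional text.
#' @export
record_collection <- function(db, sample_id, collector_id = NULL, date = NULL,
                              comment = NULL) {
  authz(db, task = "b", action = "write")
  invisible(db_insert(db, "sample_collection", list(
    sample_id = sample_id, contact_id = collector_id, date = date,
    comment = comment)))
}

#' Extract DNA from one or more samples
#'
#' A DNA extraction may pool several source samples (all from the same
#' project); one trace row per source sample is stored, so the original
#' samples remain reconstructable from the DNA.
#'
#' @param db A database handle.
#' @param samples Integer vector of source sample ids (non-empty).
#' @param protocol_id Optional extraction protocol.
#' @param date Optional ISO date.
#' @param operator_id Optional contact performing the extraction.
#' @param concentration Optional measured concentration.
#' @return The DNA (extraction group) id, invisibly.
#' @export
extract_dna <- function(db, samples, protocol_id = NULL, date = NULL,
                        operator_id = NULL, concentration = NULL) {
  authz(db, task = "b", action = "write")
  samples <- as.integer(samples)
  if (length(samples) == 0L)
    stop_genolims("at least one source sample is required", "genolims_invalid_value")
  proj <- dbGetQuery(db$con, sprintf(
    "SELECT DISTINCT project_id FROM samples WHERE sample_id IN (%s)",
    paste(samples, collapse = ",")))$project_id
  if (length(proj) > 1L)
    stop_genolims("source samples span several projects; pooling across projects is not allowed",
                  "genolims_cross_project")
  lims_transaction(db, {
    dna_id <- db_next_id(db, "dna_extraction", "dna_id")
    db_insert_many(db, "dna_extraction", lapply(samples, function(s) list(
      dna_id = dna_id, sample_id = s, protocol_id = protocol_id,
      date = date, concentration = concentration, contact_id = operator_id)))
    invisible(dna_id)
  })
}

#' Extract DNA for many sample groups at once
#'
#' Vectorised variant of [extract_dna()]: each element of `groups` is the
#' source-sample vector of one extraction (pooled when longer than one).
#'
#' @param db A database handle.
#' @param groups List of integer vectors of sample ids.
#' @inheritParams extract_dna
#' @return Integer vector of DNA ids, parallel to `groups`.
#' @export
extract_dna_batch <- function(db, groups, protocol_id = NULL, date = NULL,
                              operator_id = NULL) {
  authz(db, task = "b", action = "write")
  if (length(groups) == 0L) return(integer(0))
  if (any(lengths(groups) == 0L))
    stop_genolims("at least one source sample is required per group",
                  "genolims_invalid_value")
  all_samples <- as.integer(unlist(groups))
  proj <- dbGetQuery(db$con, sprintf(
    "SELECT sample_id, project_id FROM samples WHERE sample_id IN (%s)",
    paste(unique(all_samples), collapse = ",")))
  proj_of <- proj$project_id[match(all_samples, proj$sample_id)]
  grp_idx <- rep(seq_along(groups), lengths(groups))
  if (any(vapply(split(proj_of, grp_idx), function(p)
    length(unique(p)) > 1L, TRUE)))
    stop_genolims("a group pools samples from several projects",
                  "genolims_cross_project")
  lims_transaction(db, {
    first <- db_next_id(db, "dna_extraction", "dna_id")
    dna_ids <- first + seq_along(groups) - 1L
    db_insert_many(db, "dna_extraction", data.frame(
      dna_id = dna_ids[grp_idx], sample_id = all_samples,
      protocol_id = if (is.null(protocol_id)) NA_integer_ else protocol_id,
      date = if (is.null(date)) NA_character_ else date,
      contact_id = if (is.null(operator_id)) NA_integer_ else operator_id))
    dna_ids
  })
}

#' Source samples of a DNA extraction group
#' @param db A database handle.
#' @param dna_id DNA id.
#' @export
dna_sources <- function(db, dna_id) {
  authz(db, task = "c", action = "read")
  dbGetQuery(db$con,
    "SELECT * FROM dna_extraction WHERE dna_id = ? ORDER BY dna_extraction_id",
    params = list(dna_id))
}

dna_project <- function(db, dna_ids) {
  if (length(dna_ids) == 0L) return(integer(0))
  dbGetQuery(db$con, sprintf(
    "SELECT DISTINCT s.project_id FROM dna_extraction d
       JOIN samples s ON s.sample_id = d.sample_id
      WHERE d.dna_id IN (%s)", paste(dna_ids, collapse = ",")))$project_id
}

# row-major plate order A1..A12, B1.., .., H12
auto_wells <- function(n) {
  if (n > 96L)
    stop_genolims("more than 96 amplified samples: provide explicit wells",
                  "genolims_invalid_value")
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 12L + 1L], i %% 12L + 1L)
}

#' Set up a PCR amplification
#'
#' Records one PCR run over a set of DNA extractions and a set of markers
#' (primers).  Well labels default to row-major plate order (`A1`..`H12`)
#' when omitted.
#'
#' @param db A database handle.
#' @param dnas Integer vector of DNA ids (non-empty).
#' @param markers `PRIMER` codes (ids or short names), non-empty.
#' @param protocol_id Optional PCR protocol.
#' @param date Optional ISO date.
#' @param wells Optional character vector of well labels, one per DNA.
#' @param marker_types Optional `MARKER_TYPE` codes parallel to `markers`.
#' @param comment Optional text.
#' @return The PCR id, invisibly.
#' @export
setup_pcr <- function(db, dnas, markers, protocol_id = NULL, date = NULL,
                      wells = NULL, marker_types = NULL, comment = NULL) {
  authz(db, task = "b", action = "write")
  dnas <- unique(as.integer(dnas))
  if (length(dnas) == 0L || length(markers) == 0L)
    stop_genolims("both DNA and marker lists must be non-empty",
                  "genolims_invalid_value")
  marker_ids <- vapply(markers, function(m)
    code_id_for(db, "PRIMER", m), integer(1))
  mt_ids <- if (is.null(marker_types)) rep(NA_integer_, length(markers))
  else vapply(marker_types, function(m)
    code_id_for(db, "MARKER_TYPE", m), integer(1))
  if (is.null(wells)) wells <- auto_wells(length(dnas))
  else if (length(wells) != length(dnas))
    stop_genolims("wells must be parallel to dnas", "genolims_invalid_value")
  lims_transaction(db, {
    pcr <- db_insert(db, "pcr_amplification",
                     list(protocol_id = protocol_id, date = date,
                          comment = comment))
    db_insert_many(db, "pcr_markers", lapply(seq_along(marker_ids), function(i)
      list(pcr_id = pcr, primer_id = marker_ids[[i]],
           marker_type_id = mt_ids[[i]])))
    db_insert_many(db, "amplified_samples", lapply(seq_along(dnas), function(i)
      list(pcr_id = pcr, dna_id = dnas[[i]], well = wells[[i]])))
    invisible(pcr)
  })
}

#' Record a validation of DNA or a PCR product
#'
#' @param db A database handle.
#' @param target_type `"dna"` or `"pcr"`.
#' @param target_id DNA id or PCR id.
#' @param result One of `pass`, `fail`, `ambiguous`.
#' @param gel_image Optional path of a gel image, blob-stored byte-exactly.
#' @param comment Optional text.
#' @return The validation id, invisibly.
#' @export
record_validation <- function(db, target_type, target_id, result,
                              gel_image = NULL, comment = NULL) {
  authz(db, task = "b", action = "write")
  target_type <- match.arg(target_type, c("dna", "pcr"))
  if (!result %in% c("pass", "fail", "ambiguous"))
    stop_genolims("result must be one of pass, fail, ambiguous",
                  "genolims_invalid_value")
  exists <- if (target_type == "dna")
    nrow(dbGetQuery(db$con, "SELECT 1 FROM dna_extraction WHERE dna_id = ? LIMIT 1",
                    params = list(target_id))) > 0L
  else !is.null(db_get(db, "pcr_amplification", target_id))
  if (!exists)
    stop_genolims(sprintf("no %s with id %s", target_type, target_id),
                  "genolims_not_found")
  lims_transaction(db, {
    vid <- db_insert(db, "validation", list(
      target_type = target_type, target_id = as.integer(target_id),
      result = result, comment = comment))
    if (!is.null(gel_image)) {
      bid <- store_blob(db, gel_image)
      db_insert(db, "gel_images", list(validation_id = vid, blob_id = bid))
    }
    invisible(vid)
  })
}

#' Record an electrophoresis run with its raw files
#'
#' Raw files (gel pictures, chromatograms such as AB1/SCF, archives) are
#' stored as independent opaque blobs attached to the run, regardless of
#' the sequencer architecture that produced them.
#'
#' @param db A database handle.
#' @param pcr_id The amplification the run belongs to.
#' @param method Optional `METHOD` code (id or short name).
#' @param machine Optional instrument name.
#' @param date Optional ISO date.
#' @param raw_files Character vector of file paths (may be empty).
#' @return The run id, invisibly.
#' @export
record_electrophoresis <- function(db, pcr_id, method = NULL, machine = NULL,
                                   date = NULL, raw_files = character(0)) {
  authz(db, task = "b", action = "write")
  if (is.null(db_get(db, "pcr_amplification", pcr_id)))
    stop_genolims(paste0("no PCR with id ", pcr_id), "genolims_not_found")
  lims_transaction(db, {
    run <- db_insert(db, "electrophoresis", list(
      pcr_id = pcr_id, method_id = code_id_for(db, "METHOD", method),
      machine = machine, date = date))
    for (f in raw_files) store_blob(db, f, run_id = run)
    invisible(run)
  })
}

# amplified entries of a project for one marker, with resolvable names:
# the DNA id and the external ids of the DNA's source samples
project_amplified <- function(db, project_id, marker_id) {
  dbGetQuery(db$con,
    "SELECT DISTINCT a.amplified_id, a.dna_id
       FROM amplified_samples a
       JOIN pcr_markers m ON m.pcr_id = a.pcr_id
       JOIN dna_extraction d ON d.dna_id = a.dna_id
       JOIN samples s ON s.sample_id = d.sample_id
      WHERE s.project_id = ? AND m.primer_id = ?
      ORDER BY a.amplified_id",
    params = list(project_id, marker_id))
}

# Resolve record names to amplified entries: the first whitespace-delimited
# token is matched (a) against the DNA id, then (b) against a source-sample
# external id; ambiguity and failure are errors.
resolve_seq_names <- function(db, names, amp) {
  tokens <- vapply(strsplit(names, "\\s+"), `[[`, "", 1L)
  ext <- if (nrow(amp)) dbGetQuery(db$con, sprintf(
    "SELECT DISTINCT d.dna_id, t.external_id
       FROM dna_extraction d
       JOIN transfer t ON t.organism_id =
            (SELECT organism_id FROM samples WHERE sample_id = d.sample_id)
      WHERE d.dna_id IN (%s)", paste(unique(amp$dna_id), collapse = ",")))
  else data.frame(dna_id = integer(0), external_id = character(0))

  vapply(tokens, function(tok) {
    by_dna <- amp$amplified_id[as.character(amp$dna_id) == tok]
    if (length(by_dna) == 1L) return(by_dna)
    if (length(by_dna) > 1L)
      stop_genolims(paste0("ambiguous record id '", tok, "' (several amplified entries)"),
                    "genolims_ambiguous_id")
    dnas <- unique(ext$dna_id[ext$external_id == tok])
    hits <- amp$amplified_id[amp$dna_id %in% dnas]
    if (length(hits) == 0L)
      stop_genolims(paste0("unresolvable record id '", tok, "'"),
                    "genolims_unresolved_id")
    if (length(hits) > 1L)
      stop_genolims(paste0("ambiguous record id '", tok, "'"),
                    "genolims_ambiguous_id")
    hits
  }, integer(1), USE.NAMES = FALSE)
}

#' Import final sequences from a FASTA file
#'
#' One sequence result is stored per FASTA record.  Record identifiers
#' (first whitespace-delimited token) are resolved first against DNA ids,
#' then against sample external ids, within the project's amplified
#' entries for the given marker.  The import is all-or-nothing: a single
#' unresolvable identifier aborts and nothing is persisted.
#'
#' @param db A database handle.
#' @param project Project id or name.
#' @param file FASTA file path.
#' @param marker `PRIMER` code (id or short name).
#' @param software Optional `SOFTWARE` code naming the base-calling tool.
#' @return Integer vector of new sequence ids.
#' @export
import_sequences <- function(db, project, file, marker, software = NULL) {
  authz(db, task = "b", action = "write")
  project_id <- project_id_for(db, project)
  marker_id <- code_id_for(db, "PRIMER", marker)
  set <- tryCatch(Biostrings::readBStringSet(file),
                  error = function(e)
                    stop_genolims(paste0("malformed FASTA: ", conditionMessage(e)),
                                  "genolims_bad_fasta"))
  if (length(set) == 0L)
    stop_genolims("FASTA file contains no records", "genolims_bad_fasta")
  bases <- as.character(set)
  for (b in bases) assert_iupac(b)
  amp <- project_amplified(db, project_id, marker_id)
  lims_transaction(db, {
    amp_ids <- resolve_seq_names(db, names(set), amp)
    db_insert_many(db, "sequences", lapply(seq_along(amp_ids), function(i) list(
      amplified_id = amp_ids[[i]], primer_id = marker_id, bases = bases[[i]],
      software_id = code_id_for(db, "SOFTWARE", software),
      length = nchar(bases[[i]]))))
  })
}

# missing-allele encoding on disk: empty cell or "0"
msat_cell_value <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || !nzchar(x) || x == "0") return(NA_integer_)
  v <- suppressWarnings(as.integer(x))
  if (is.na(v) || v <= 0)
    stop_genolims(paste0("invalid allele value '", x,
                         "' (positive integer base pairs expected)"),
                  "genolims_invalid_value")
  v
}

# map row keys (dna id first, then sample external id) to dna ids of a project
resolve_row_keys <- function(db, keys, project_id) {
  dna <- dbGetQuery(db$con,
    "SELECT DISTINCT d.dna_id, d.sample_id FROM dna_extraction d
       JOIN samples s ON s.sample_id = d.sample_id
      WHERE s.project_id = ?", params = list(project_id))
  ext <- if (nrow(dna)) dbGetQuery(db$con, sprintf(
    "SELECT DISTINCT d.dna_id, t.external_id
       FROM dna_extraction d
       JOIN transfer t ON t.organism_id =
            (SELECT organism_id FROM samples WHERE sample_id = d.sample_id)
      WHERE d.dna_id IN (%s)", paste(unique(dna$dna_id), collapse = ",")))
  else data.frame(dna_id = integer(0), external_id = character(0))
  vapply(as.character(keys), function(k) {
    if (k %in% as.character(dna$dna_id)) return(as.integer(k))
    hits <- unique(ext$dna_id[ext$external_id == k])
    if (length(hits) == 0L)
      stop_genolims(paste0("unresolvable row key '", k, "'"),
                    "genolims_unresolved_id")
    if (length(hits) > 1L)
      stop_genolims(paste0("ambiguous row key '", k, "' (several DNA extractions)"),
                    "genolims_ambiguous_id")
    hits
  }, integer(1), USE.NAMES = FALSE)
}

#' Import a microsatellite genotype matrix
#'
#' Rows are samples (keyed by DNA id or sample external id), columns are
#' markers: two allele columns per marker (`<marker>_1`, `<marker>_2`) for
#' diploid data, one (`<marker>`) for haploid.  Empty cells and `"0"` are
#' missing.  One result is stored per (row, marker) cell with any
#' non-missing allele; structural errors (wrong column count, unknown row
#' key) abort the whole import.
#'
#' @param db A database handle.
#' @param project Project id or name.
#' @param table CSV file path or a data.frame; first column is the row key.
#' @param markers Ordered `PRIMER` codes (ids or short names).
#' @param ploidy `"diploid"` or `"haploid"`.
#' @param software Optional `SOFTWARE` code.
#' @return Integer vector of new microsatellite result ids.
#' @export
import_microsat_matrix <- function(db, project, table, markers,
                                   ploidy = c("diploid", "haploid"),
                                   software = NULL) {
  authz(db, task = "b", action = "write")
  ploidy <- match.arg(ploidy)
  project_id <- project_id_for(db, project)
  tab <- if (is.character(table))
    read.csv(table, check.names = FALSE, colClasses = "character") else table
  per <- if (ploidy == "diploid") 2L else 1L
  want <- 1L + per * length(markers)
  if (ncol(tab) != want)
    stop_genolims(sprintf(
      "matrix has %d columns but %d markers x %s ploidy require %d",
      ncol(tab), length(markers), ploidy, want), "genolims_structural_error")
  marker_ids <- vapply(markers, function(m) code_id_for(db, "PRIMER", m),
                       integer(1))
  software_id <- code_id_for(db, "SOFTWARE", software)
  lims_transaction(db, {
    dna_ids <- resolve_row_keys(db, tab[[1L]], project_id)
    recs <- list()
    for (i in seq_len(nrow(tab))) {
      for (j in seq_along(marker_ids)) {
        a1 <- msat_cell_value(tab[[1L + (j - 1L) * per + 1L]][[i]])
        a2 <- if (per == 2L) msat_cell_value(tab[[1L + (j - 1L) * per + 2L]][[i]])
        else NA_integer_
        if (is.na(a1) && is.na(a2)) next
        recs[[length(recs) + 1L]] <- list(
          dna_id = dna_ids[[i]], primer_id = marker_ids[[j]],
          allele1 = a1, allele2 = a2, software_id = software_id,
          project_id = project_id)
      }
    }
    db_insert_many(db, "microsatellites", recs)
  })
}

#' Export a step template for the next workflow step
#'
#' Emits a spreadsheet whose columns are exactly what the following step's
#' import accepts, pre-filled with the project's eligible records: data is
#' pipelined from one step to the next.
#'
#' @param db A database handle.
#' @param step One of `prepare_samples` (template for [import_extractions()]),
#'   `extract_dna` (template for [import_pcr_sheet()]), `setup_pcr`
#'   (template for result import).
#' @param project Project id or name.
#' @param file Optional CSV path to write.
#' @return The template as a data.frame, invisibly when `file` is given.
#' @export
export_step_template <- function(db, step, project, file = NULL) {
  authz(db, task = "e", action = "read")
  project_id <- project_id_for(db, project)
  tmpl <- switch(step,
    prepare_samples = {
      rows <- dbGetQuery(db$con,
        "SELECT s.sample_id,
                (SELECT external_id FROM transfer t
                  WHERE t.organism_id = s.organism_id
                  ORDER BY t.transfer_id LIMIT 1) AS sample
           FROM samples s WHERE s.project_id = ? ORDER BY s.sample_id",
        params = list(project_id))
      n <- nrow(rows)
      data.frame(sample = ifelse(is.na(rows$sample),
                                 as.character(rows$sample_id), rows$sample),
                 protocol = rep("", n), date = rep("", n),
                 operator = rep("", n), concentration = rep("", n),
                 dna_group = rep("", n), stringsAsFactors = FALSE)
    },
    extract_dna = {
      dna <- dbGetQuery(db$con,
        "SELECT DISTINCT d.dna_id FROM dna_extraction d
           JOIN samples s ON s.sample_id = d.sample_id
          WHERE s.project_id = ? ORDER BY d.dna_id", params = list(project_id))
      data.frame(dna = dna$dna_id, well = "", stringsAsFactors = FALSE)
    },
    setup_pcr = {
      dbGetQuery(db$con,
        "SELECT a.dna_id AS dna, c.short_name AS marker, a.well
           FROM amplified_samples a
           JOIN pcr_markers m ON m.pcr_id = a.pcr_id
           JOIN codes c ON c.code_id = m.primer_id
           JOIN dna_extraction d ON d.dna_id = a.dna_id
           JOIN samples s ON s.sample_id = d.sample_id
          WHERE s.project_id = ?
          GROUP BY a.amplified_id, m.pcr_marker_id
          ORDER BY a.amplified_id", params = list(project_id))
    },
    stop_genolims(paste0("unknown workflow step: ", step), "genolims_unknown_step"))
  if (!is.null(file)) {
    write.csv(tmpl, file, row.names = FALSE)
    return(invisible(tmpl))
  }
  tmpl
}

# find-or-create helpers used by sheet imports and the batch loader
contact_id_by_name <- function(db, name, create = TRUE) {
  if (is.null(name) || is.na(name) || !nzchar(name)) return(NULL)
  r <- dbGetQuery(db$con, "SELECT contact_id FROM contacts WHERE name = ? LIMIT 1",
                  params = list(name))
  if (nrow(r)) return(r$contact_id)
  if (!create) stop_genolims(paste0("no contact: ", name), "genolims_not_found")
  db_insert(db, "contacts", list(name = name))
}

protocol_id_by_name <- function(db, name, type = "unknown", create = TRUE) {
  if (is.null(name) || is.na(name) || !nzchar(name)) return(NULL)
  r <- dbGetQuery(db$con, "SELECT protocol_id FROM protocols WHERE name = ? LIMIT 1",
                  params = list(name))
  if (nrow(r)) return(r$protocol_id)
  if (!create) stop_genolims(paste0("no protocol: ", name), "genolims_not_found")
  db_insert(db, "protocols", list(
    name = name, protocol_type_id = code_id_for(db, "PROTOCOL_TYPE", type)))
}

#' Import DNA extractions from a step sheet
#'
#' Consumes the spreadsheet produced by
#' `export_step_template("prepare_samples", ...)`: one extraction per row,
#' rows sharing a non-empty `dna_group` value pooled into one extraction.
#' Sample keys resolve like FASTA record ids (sample external id or sample
#' id).  All-or-nothing.
#'
#' @param db A database handle.
#' @param project Project id or name.
#' @param sheet CSV path or data.frame with columns `sample`, `protocol`,
#'   `date`, `operator`, `concentration`, `dna_group`.
#' @return Integer vector of new DNA ids.
#' @export
import_extractions <- function(db, project, sheet) {
  authz(db, task = "b", action = "write")
  project_id <- project_id_for(db, project)
  tab <- if (is.character(sheet))
    read.csv(sheet, check.names = FALSE, colClasses = "character") else sheet
  need <- c("sample", "protocol", "date", "operator", "concentration", "dna_group")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_genolims(paste0("extraction sheet lacks columns: ",
                         paste(missing, collapse = ", ")),
                  "genolims_structural_error")
  smp <- dbGetQuery(db$con,
    "SELECT s.sample_id, t.external_id FROM samples s
       LEFT JOIN transfer t ON t.organism_id = s.organism_id
      WHERE s.project_id = ?", params = list(project_id))
  resolve_sample <- function(k) {
    k <- as.character(k)
    hit <- unique(smp$sample_id[!is.na(smp$external_id) & smp$external_id == k])
    if (length(hit) == 1L) return(hit)
    if (length(hit) > 1L)
      stop_genolims(paste0("ambiguous sample key '", k, "'"), "genolims_ambiguous_id")
    if (k %in% as.character(smp$sample_id)) return(as.integer(k))
    stop_genolims(paste0("unresolvable sample key '", k, "'"),
                  "genolims_unresolved_id")
  }
  lims_transaction(db, {
    ids <- vapply(tab$sample, resolve_sample, integer(1), USE.NAMES = FALSE)
    grp <- as.character(tab$dna_group)
    grp[is.na(grp) | !nzchar(grp)] <- paste0("\r#", seq_len(nrow(tab)))[is.na(grp) | !nzchar(grp)]
    out <- integer(0)
    for (g in unique(grp)) {
      rows <- which(grp == g)
      r1 <- rows[[1L]]
      conc <- suppressWarnings(as.numeric(tab$concentration[[r1]]))
      out <- c(out, extract_dna(
        db, ids[rows],
        protocol_id = protocol_id_by_name(db, tab$protocol[[r1]], "extraction"),
        date = chr_or_null(tab$date[[r1]]),
        operator_id = contact_id_by_name(db, tab$operator[[r1]]),
        concentration = if (is.na(conc)) NULL else conc))
    }
    out
  })
}

#' Import a PCR set-up sheet
#'
#' Consumes the `extract_dna` step template: one amplified entry per row
#' (`dna`, `well`), run-level markers/protocol/date given as arguments.
#'
#' @param db A database handle.
#' @param project Project id or name (sanity check on the DNA ids).
#' @param sheet CSV path or data.frame with columns `dna`, `well`.
#' @param markers `PRIMER` codes for the run.
#' @param protocol_id,date Optional run metadata.
#' @return The PCR id, invisibly.
#' @export
import_pcr_sheet <- function(db, project, sheet, markers, protocol_id = NULL,
                             date = NULL) {
  authz(db, task = "b", action = "write")
  project_id <- project_id_for(db, project)
  tab <- if (is.character(sheet))
    read.csv(sheet, check.names = FALSE, colClasses = "character") else sheet
  if (!all(c("dna", "well") %in% names(tab)))
    stop_genolims("PCR sheet needs columns dna, well", "genolims_structural_error")
  dnas <- as.integer(tab$dna)
  if (!all(dna_project(db, dnas) == project_id))
    stop_genolims("sheet contains DNA from another project", "genolims_cross_project")
  wells <- as.character(tab$well)
  if (all(!nzchar(wells) | is.na(wells))) wells <- NULL
  setup_pcr(db, dnas, markers, protocol_id = protocol_id, date = date,
            wells = wells)
}
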