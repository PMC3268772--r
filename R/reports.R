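# The thirteen predefined report types, generated from current database
# state through external plain-text templates (so layouts can be changed
# without touching code).  Every numeric cell equals a direct query;
# report generation never writes.

REPORT_TYPES <- list(
  project_list            = list(params = character(0),
    description = "list of projects with sample counts"),
  contact_list            = list(params = character(0),
    description = "list of contacts"),
  individual_list         = list(params = character(0),
    description = "list of individuals with external ids"),
  project_samples_storage = list(params = "project",
    description = "samples of a project with full storage paths"),
  project_dna_storage     = list(params = "project",
    description = "DNA of a project with full storage paths"),
  sequence_stats_marker   = list(params = "marker",
    description = "sequence statistics for one marker"),
  sequence_stats_project  = list(params = "project",
    description = "per-marker sequence statistics of a project"),
  sequence_stats_lab      = list(params = character(0),
    description = "per-marker sequence statistics, whole lab"),
  microsat_stats_marker   = list(params = "marker",
    description = "microsatellite statistics for one marker"),
  microsat_stats_project  = list(params = "project",
    description = "per-marker microsatellite statistics of a project"),
  microsat_stats_lab      = list(params = character(0),
    description = "per-marker microsatellite statistics, whole lab"),
  lab_data_volume         = list(params = character(0),
    description = "record totals over the entire lab"),
  sample_distribution     = list(params = "project",
    description = "sample counts per material type of a project"))

#' The registry of predefined report types
#'
#' @return A data.frame with one row per report type (13 in total): name,
#'   required parameters, description.
#' @export
list_report_types <- function() {
  data.frame(
    type = names(REPORT_TYPES),
    params = vapply(REPORT_TYPES, function(x)
      paste(x$params, collapse = ","), ""),
    description = vapply(REPORT_TYPES, `[[`, "", "description"),
    row.names = NULL, stringsAsFactors = FALSE)
}

report_template_path <- function(type) {
  system.file("templates", paste0(type, ".txt"), package = "genolims",
              mustWork = TRUE)
}

storage_path_of <- function(db, item_type, item_id) {
  p <- tryCatch(locate_item(db, item_type, item_id),
                genolims_error = function(e) NULL)
  if (is.null(p)) "" else format_storage_path(p)
}

seq_stats_query <- function(db, where, params) {
  dbGetQuery(db$con, paste0(
    "SELECT c.short_name AS marker, COUNT(*) AS n_sequences,
            MIN(q.length) AS min_length,
            ROUND(AVG(q.length), 2) AS mean_length,
            MAX(q.length) AS max_length
       FROM sequences q
       JOIN codes c ON c.code_id = q.primer_id ", where,
    " GROUP BY q.primer_id ORDER BY c.short_name"), params = params)
}

msat_stats_query <- function(db, where, params) {
  dbGetQuery(db$con, paste0(
    "SELECT c.short_name AS marker, COUNT(*) AS n_genotypes,
            COUNT(DISTINCT m.allele1) + COUNT(DISTINCT m.allele2) AS n_allele_values,
            MIN(MIN(m.allele1), MIN(m.allele2)) AS min_allele,
            MAX(MAX(m.allele1), MAX(m.allele2)) AS max_allele
       FROM microsatellites m
       JOIN codes c ON c.code_id = m.primer_id ", where,
    " GROUP BY m.primer_id ORDER BY c.short_name"), params = params)
}

report_body <- function(db, type, project_id = NULL, marker_id = NULL) {
  switch(type,
    project_list = dbGetQuery(db$con,
      "SELECT p.name, c.short_name AS purpose, p.start_date,
              (SELECT COUNT(*) FROM samples s
                WHERE s.project_id = p.project_id) AS n_samples
         FROM projects p LEFT JOIN codes c ON c.code_id = p.purpose_id
        ORDER BY p.project_id"),
    contact_list = dbGetQuery(db$con,
      "SELECT ct.name, u.name AS unit, ct.email, ct.phone
         FROM contacts ct LEFT JOIN unit u ON u.unit_id = ct.unit_id
        ORDER BY ct.contact_id"),
    individual_list = dbGetQuery(db$con,
      "SELECT t.id_system, t.external_id, sp.short_name AS species,
              br.short_name AS breed, sx.short_name AS sex
         FROM organisms o
         JOIN transfer t ON t.organism_id = o.organism_id
         LEFT JOIN codes sp ON sp.code_id = o.species_id
         LEFT JOIN codes br ON br.code_id = o.breed_id
         LEFT JOIN codes sx ON sx.code_id = o.sex_id
        ORDER BY o.organism_id, t.transfer_id"),
    project_samples_storage = {
      rows <- dbGetQuery(db$con,
        "SELECT s.sample_id,
                (SELECT external_id FROM transfer t
                  WHERE t.organism_id = s.organism_id
                  ORDER BY t.transfer_id LIMIT 1) AS individual,
                mt.short_name AS material, vt.short_name AS vessel,
                s.amount, s.amount_unit
           FROM samples s
           LEFT JOIN codes mt ON mt.code_id = s.material_type_id
           LEFT JOIN codes vt ON vt.code_id = s.vessel_type_id
          WHERE s.project_id = ? ORDER BY s.sample_id",
        params = list(project_id))
      rows$storage <- vapply(rows$sample_id, function(i)
        storage_path_of(db, "sample", i), "")
      rows
    },
    project_dna_storage = {
      rows <- dbGetQuery(db$con,
        "SELECT d.dna_id, GROUP_CONCAT(d.sample_id) AS source_samples,
                MAX(d.date) AS date, MAX(d.concentration) AS concentration
           FROM dna_extraction d
           JOIN samples s ON s.sample_id = d.sample_id
          WHERE s.project_id = ?
          GROUP BY d.dna_id ORDER BY d.dna_id", params = list(project_id))
      rows$storage <- vapply(rows$dna_id, function(i)
        storage_path_of(db, "dna", i), "")
      rows
    },
    sequence_stats_marker = seq_stats_query(db, "WHERE q.primer_id = ?",
                                            list(marker_id)),
    sequence_stats_project = seq_stats_query(db,
      "JOIN amplified_samples a ON a.amplified_id = q.amplified_id
       JOIN dna_extraction d ON d.dna_id = a.dna_id
       JOIN samples s ON s.sample_id = d.sample_id
       WHERE s.project_id = ?", list(project_id)),
    sequence_stats_lab = seq_stats_query(db, "", NULL),
    microsat_stats_marker = msat_stats_query(db, "WHERE m.primer_id = ?",
                                             list(marker_id)),
    microsat_stats_project = msat_stats_query(db, "WHERE m.project_id = ?",
                                              list(project_id)),
    microsat_stats_lab = msat_stats_query(db, "", NULL),
    lab_data_volume = {
      cnt <- function(sql) dbGetQuery(db$con, sql)[[1L]]
      data.frame(
        category = c("projects", "individuals", "samples", "dna_extractions",
                     "pcr_amplifications", "sequences", "microsatellites",
                     "raw_files", "raw_bytes"),
        count = c(cnt("SELECT COUNT(*) FROM projects"),
                  cnt("SELECT COUNT(*) FROM organisms"),
                  cnt("SELECT COUNT(*) FROM samples"),
                  cnt("SELECT COUNT(DISTINCT dna_id) FROM dna_extraction"),
                  cnt("SELECT COUNT(*) FROM pcr_amplification"),
                  cnt("SELECT COUNT(*) FROM sequences"),
                  cnt("SELECT COUNT(*) FROM microsatellites"),
                  cnt("SELECT COUNT(*) FROM blobs"),
                  cnt("SELECT COALESCE(SUM(size), 0) FROM blobs")),
        stringsAsFactors = FALSE)
    },
    sample_distribution = dbGetQuery(db$con,
      "SELECT mt.short_name AS material_type, COUNT(*) AS n_samples
         FROM samples s LEFT JOIN codes mt ON mt.code_id = s.material_type_id
        WHERE s.project_id = ?
        GROUP BY s.material_type_id ORDER BY mt.short_name",
      params = list(project_id)),
    stop_genolims(paste0("unknown report type: ", type),
                  "genolims_unknown_report"))
}

#' Generate a predefined report
#'
#' Renders one of the thirteen report types from current database state.
#' Counts and statistics are computed by direct queries at generation
#' time; storage locations are rendered as full root-to-leaf paths.
#'
#' @param db A database handle.
#' @param type One of `list_report_types()$type`.
#' @param project Project id or name (for per-project types).
#' @param marker `PRIMER` code (for per-marker types).
#' @param file Optional output path.
#' @param format `"text"` (template header + table) or `"csv"` (table
#'   only); applies when writing to `file`.
#' @return An object of class `genolims_report` with elements `type`,
#'   `header` (rendered template lines) and `body` (data.frame).
#' @export
generate_report <- function(db, type, project = NULL, marker = NULL,
                            file = NULL, format = c("text", "csv")) {
  authz(db, task = "d", action = "read")
  format <- match.arg(format)
  spec <- REPORT_TYPES[[type]]
  if (is.null(spec))
    stop_genolims(paste0("unknown report type: ", type),
                  "genolims_unknown_report")
  project_id <- marker_id <- NULL
  if ("project" %in% spec$params) {
    if (is.null(project))
      stop_genolims(paste0("report '", type, "' requires a project"),
                    "genolims_missing_param")
    project_id <- project_id_for(db, project)
  }
  if ("marker" %in% spec$params) {
    if (is.null(marker))
      stop_genolims(paste0("report '", type, "' requires a marker"),
                    "genolims_missing_param")
    marker_id <- code_id_for(db, "PRIMER", marker)
    if (is.na(marker_id) ||
        nrow(dbGetQuery(db$con, "SELECT 1 FROM codes WHERE code_id = ?",
                        params = list(marker_id))) == 0L)
      stop_genolims(paste0("unknown marker: ", marker), "genolims_not_found")
  }
  body <- report_body(db, type, project_id, marker_id)

  vars <- list(
    date = format(Sys.Date()),
    project = if (!is.null(project_id))
      dbGetQuery(db$con, "SELECT name FROM projects WHERE project_id = ?",
                 params = list(project_id))$name else "",
    marker = if (!is.null(marker_id)) code_short(db, marker_id) else "")
  header <- readLines(report_template_path(type), warn = FALSE)
  header <- header[!grepl("{{TABLE}}", header, fixed = TRUE)]
  for (nm in names(vars))
    header <- gsub(paste0("{{", nm, "}}"), vars[[nm]], header, fixed = TRUE)

  rep <- structure(list(type = type, header = header, body = body),
                   class = "genolims_report")
  if (!is.null(file)) {
    if (format == "csv") {
      write.csv(body, file, row.names = FALSE)
    } else {
      con <- file(file, "w")
      on.exit(close(con))
      writeLines(header, con)
      write.csv(body, con, row.names = FALSE)
    }
  }
  rep
}

#' @export
print.genolims_report <- function(x, ...) {
  writeLines(x$header)
  print(x$body, row.names = FALSE)
  invisible(x)
}
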