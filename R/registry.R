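# Registries: units/contacts/protocols (lab resources), projects,
# individuals (organisms with arbitrary external identifier systems) and
# samples.  trace_sample() assembles the full association bundle around a
# sample, mirroring the tracking model in which the sample is the central
# entry point.

#' Add an organisational unit
#' @param db A database handle.
#' @param name Unique unit name.
#' @param description Optional text.
#' @return Unit id, invisibly.
#' @export
add_unit <- function(db, name, description = NULL) {
  authz(db, task = "f", action = "write")
  invisible(db_insert(db, "unit", list(name = name, description = description)))
}

#' Add a contact (lab member, collaborator)
#' @param db A database handle.
#' @param name Person name.
#' @param unit_id Optional unit.
#' @param country,language Optional codes (`COUNTRY`/`LANGUAGE`; id or
#'   short name).
#' @param email,phone Optional text.
#' @return Contact id, invisibly.
#' @export
add_contact <- function(db, name, unit_id = NULL, country = NULL,
                        language = NULL, email = NULL, phone = NULL) {
  authz(db, task = "f", action = "write")
  invisible(db_insert(db, "contacts", list(
    name = name, unit_id = unit_id,
    country_id = code_id_for(db, "COUNTRY", country),
    language_id = code_id_for(db, "LANGUAGE", language),
    email = email, phone = phone)))
}

#' Add an experimental protocol
#'
#' The protocol document, if given, is stored as an opaque blob.
#'
#' @param db A database handle.
#' @param name Protocol name, unique within its type.
#' @param protocol_type `PROTOCOL_TYPE` code (id or short name).
#' @param document Optional path of a document file to blob-store.
#' @param description Optional text.
#' @return Protocol id, invisibly.
#' @export
add_protocol <- function(db, name, protocol_type, document = NULL,
                         description = NULL) {
  authz(db, task = "f", action = "write")
  lims_transaction(db, {
    blob_id <- if (!is.null(document)) store_blob(db, document) else NULL
    invisible(db_insert(db, "protocols", list(
      name = name,
      protocol_type_id = code_id_for(db, "PROTOCOL_TYPE", protocol_type),
      blob_id = blob_id, description = description)))
  })
}

#' Create a project
#' @param db A database handle.
#' @param name Unique project name.
#' @param purpose `PURPOSE` code: `sequencing` or `genotyping` (id or short
#'   name).
#' @param owner_contact_id Optional owning contact.
#' @param start_date Optional ISO date.
#' @return Project id, invisibly.
#' @export
add_project <- function(db, name, purpose, owner_contact_id = NULL,
                        start_date = NULL) {
  authz(db, task = "b", action = "write")
  invisible(db_insert(db, "projects", list(
    name = name, purpose_id = code_id_for(db, "PURPOSE", purpose),
    owner_contact_id = owner_contact_id, start_date = start_date)))
}

project_id_for <- function(db, project) {
  if (is.numeric(project)) return(as.integer(project))
  r <- dbGetQuery(db$con, "SELECT project_id FROM projects WHERE name = ?",
                  params = list(as.character(project)))
  if (nrow(r) != 1L)
    stop_genolims(paste0("no project: ", project), "genolims_not_found")
  r$project_id
}

#' Register an individual (organism) under an external identifier
#'
#' Individuals of any species and breed/variety are accepted; the external
#' id ties the organism to whatever naming authority the lab uses (ear
#' tags, herd books, field collection numbers, ...).  Registration is
#' idempotent on `(id_system, external_id)`: re-registering returns the
#' existing organism unchanged, which makes batch loads re-runnable.
#'
#' @param db A database handle.
#' @param id_system Naming authority of the external id.
#' @param external_id Identifier within that system.
#' @param species `SPECIES` code (id or short name), required.
#' @param breed,sex Optional `BREED`/`SEX` codes.
#' @param birth_date Optional ISO date.
#' @param comment Optional text.
#' @return The organism id, invisibly.
#' @export
register_individual <- function(db, id_system, external_id, species,
                                breed = NULL, sex = NULL, birth_date = NULL,
                                comment = NULL) {
  authz(db, task = "b", action = "write")
  existing <- dbGetQuery(db$con,
    "SELECT organism_id FROM transfer WHERE id_system = ? AND external_id = ?",
    params = list(id_system, external_id))
  if (nrow(existing) == 1L) return(invisible(existing$organism_id))
  lims_transaction(db, {
    oid <- db_insert(db, "organisms", list(
      species_id = code_id_for(db, "SPECIES", species),
      breed_id = code_id_for(db, "BREED", breed),
      sex_id = code_id_for(db, "SEX", sex),
      birth_date = birth_date, comment = comment))
    db_insert(db, "transfer", list(organism_id = oid, id_system = id_system,
                                   external_id = external_id))
    invisible(oid)
  })
}

#' Register a batch of individuals
#'
#' Vectorised variant of [register_individual()] with the same
#' idempotence: rows whose `(id_system, external_id)` already exist map to
#' the existing organism.
#'
#' @param db A database handle.
#' @param individuals data.frame with columns `id_system`, `external_id`,
#'   `species_id` and optionally `breed_id`, `sex_id`, `birth_date`,
#'   `comment` (codes already resolved to ids).
#' @return Integer vector of organism ids, parallel to the rows.
#' @export
register_individuals <- function(db, individuals) {
  authz(db, task = "b", action = "write")
  key <- paste(individuals$id_system, individuals$external_id, sep = "\r")
  if (anyDuplicated(key))
    stop_genolims("duplicate (id_system, external_id) rows in batch",
                  "genolims_invalid_value")
  existing <- dbGetQuery(db$con,
    "SELECT organism_id, id_system, external_id FROM transfer")
  hit <- match(key, paste(existing$id_system, existing$external_id, sep = "\r"))
  out <- existing$organism_id[hit]
  new <- which(is.na(hit))
  if (length(new)) {
    lims_transaction(db, {
      cols <- intersect(c("species_id", "breed_id", "sex_id", "birth_date",
                          "comment"), names(individuals))
      oids <- db_insert_many(db, "organisms",
                             individuals[new, cols, drop = FALSE])
      db_insert_many(db, "transfer", data.frame(
        organism_id = oids,
        id_system = individuals$id_system[new],
        external_id = individuals$external_id[new]))
      out[new] <- oids
    })
  }
  out
}

#' External identifiers of an organism
#' @param db A database handle.
#' @param organism_id Organism id.
#' @export
external_ids <- function(db, organism_id) {
  authz(db, task = "c", action = "read")
  dbGetQuery(db$con,
    "SELECT id_system, external_id FROM transfer WHERE organism_id = ?
     ORDER BY transfer_id", params = list(organism_id))
}

#' Register a sample of biological material
#'
#' @param db A database handle.
#' @param organism_id Source individual.
#' @param project Project id or name; a sample belongs to exactly one
#'   project.
#' @param material_type `MATERIAL_TYPE` code (blood, tissue, ...).
#' @param vessel_type Optional `VESSEL_TYPE` code.
#' @param amount,unit Optional quantity (must be >= 0) and its unit.
#' @param comment Optional text.
#' @return Sample id, invisibly.
#' @export
register_sample <- function(db, organism_id, project, material_type,
                            vessel_type = NULL, amount = NULL, unit = NULL,
                            comment = NULL) {
  authz(db, task = "b", action = "write")
  if (!is.null(amount) && !is.na(amount) && amount < 0)
    stop_genolims("sample amount must be >= 0", "genolims_invalid_value")
  invisible(db_insert(db, "samples", list(
    organism_id = organism_id, project_id = project_id_for(db, project),
    material_type_id = code_id_for(db, "MATERIAL_TYPE", material_type),
    vessel_type_id = code_id_for(db, "VESSEL_TYPE", vessel_type),
    amount = amount, amount_unit = unit, comment = comment)))
}

#' Register a batch of samples
#'
#' Vectorised variant of [register_sample()] (one transaction, one rule
#' check pass), used for bulk entry.
#'
#' @param db A database handle.
#' @param samples data.frame with columns `organism_id`, `project_id`,
#'   `material_type_id`, and optionally `vessel_type_id`, `amount`,
#'   `amount_unit`, `comment` (code columns already resolved to ids).
#' @return Integer vector of sample ids.
#' @export
register_samples <- function(db, samples) {
  authz(db, task = "b", action = "write")
  if (!is.null(samples$amount) && any(samples$amount < 0, na.rm = TRUE))
    stop_genolims("sample amount must be >= 0", "genolims_invalid_value")
  db_insert_many(db, "samples", samples)
}

#' Consistency audit: every organism has at least one external identifier
#' @param db A database handle.
#' @return data.frame of organisms without external ids (zero rows when
#'   consistent).
#' @export
audit_external_ids <- function(db) {
  authz(db, task = "c", action = "read")
  dbGetQuery(db$con,
    "SELECT o.* FROM organisms o LEFT JOIN transfer t
       ON t.organism_id = o.organism_id
     WHERE t.transfer_id IS NULL")
}

#' Trace a sample: the full association bundle
#'
#' Assembles everything reachable from one sample through foreign keys:
#' the sample record, its individual (with all external ids), the current
#' storage path, DNA extractions derived from it, raw-data blob metadata
#' reachable through its PCRs/electrophoresis runs and validation gel
#' images, and all final sequence and microsatellite results.
#'
#' @param db A database handle.
#' @param sample_id Sample id.
#' @return A list with elements `sample`, `organism`, `external_ids`,
#'   `storage_path`, `dna`, `raw`, `sequences`, `microsatellites`
#'   (class `genolims_trace`).
#' @export
trace_sample <- function(db, sample_id) {
  authz(db, task = "c", action = "read")
  smp <- db_get(db, "samples", sample_id)
  if (is.null(smp))
    stop_genolims(paste0("no sample with id ", sample_id), "genolims_not_found")
  org <- db_get(db, "organisms", smp$organism_id)

  path <- tryCatch(locate_item(db, "sample", sample_id),
                   genolims_error = function(e) NULL)

  dna <- dbGetQuery(db$con,
    "SELECT * FROM dna_extraction WHERE dna_id IN
       (SELECT dna_id FROM dna_extraction WHERE sample_id = ?)
     ORDER BY dna_extraction_id", params = list(sample_id))
  dna_ids <- unique(dna$dna_id)

  amp <- if (length(dna_ids)) dbGetQuery(db$con, sprintf(
    "SELECT * FROM amplified_samples WHERE dna_id IN (%s) ORDER BY amplified_id",
    paste(dna_ids, collapse = ","))) else
      db_table(db, "amplified_samples")[0, ]
  pcr_ids <- unique(amp$pcr_id)

  raw_run <- if (length(pcr_ids)) dbGetQuery(db$con, sprintf(
    "SELECT b.blob_id, b.filename, b.checksum, b.size, b.run_id
       FROM blobs b JOIN electrophoresis e ON e.run_id = b.run_id
      WHERE e.pcr_id IN (%s) ORDER BY b.blob_id",
    paste(pcr_ids, collapse = ","))) else NULL
  # gel images of validations targeting this sample's DNA or PCRs
  tgt <- character(0)
  if (length(dna_ids))
    tgt <- c(tgt, sprintf("(v.target_type = 'dna' AND v.target_id IN (%s))",
                          paste(dna_ids, collapse = ",")))
  if (length(pcr_ids))
    tgt <- c(tgt, sprintf("(v.target_type = 'pcr' AND v.target_id IN (%s))",
                          paste(pcr_ids, collapse = ",")))
  raw_gel <- if (length(tgt)) dbGetQuery(db$con, sprintf(
    "SELECT b.blob_id, b.filename, b.checksum, b.size, b.run_id
       FROM blobs b JOIN gel_images g ON g.blob_id = b.blob_id
       JOIN validation v ON v.validation_id = g.validation_id
      WHERE %s ORDER BY b.blob_id", paste(tgt, collapse = " OR "))) else NULL
  raw <- unique(rbind(raw_run, raw_gel))

  seqs <- if (nrow(amp)) dbGetQuery(db$con, sprintf(
    "SELECT * FROM sequences WHERE amplified_id IN (%s) ORDER BY seq_id",
    paste(amp$amplified_id, collapse = ","))) else
      db_table(db, "sequences")[0, ]
  msats <- if (length(dna_ids)) dbGetQuery(db$con, sprintf(
    "SELECT * FROM microsatellites WHERE dna_id IN (%s) ORDER BY msat_id",
    paste(dna_ids, collapse = ","))) else
      db_table(db, "microsatellites")[0, ]

  structure(list(
    sample = smp, organism = org,
    external_ids = external_ids(db, smp$organism_id),
    storage_path = path,
    dna = dna,
    raw = if (is.null(raw)) db_table(db, "blobs",
            c("blob_id", "filename", "checksum", "size", "run_id"))[0, ] else raw,
    sequences = seqs, microsatellites = msats),
    class = "genolims_trace")
}

#' @export
print.genolims_trace <- function(x, ...) {
  cat("<sample trace> sample", x$sample$sample_id, "\n")
  ids <- paste(x$external_ids$id_system, x$external_ids$external_id,
               sep = ":", collapse = ", ")
  cat("  individual:", x$sample$organism_id, paste0("(", ids, ")"), "\n")
  cat("  storage:   ",
      if (is.null(x$storage_path)) "(not in storage)"
      else paste(x$storage_path$storage_name, collapse = " / "), "\n")
  cat("  dna extractions:", length(unique(x$dna$dna_id)),
      " raw files:", nrow(x$raw),
      " sequences:", nrow(x$sequences),
      " microsatellites:", nrow(x$microsatellites), "\n")
  invisible(x)
}
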