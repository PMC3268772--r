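# Batch migration of historical project data: a name/value configuration
# file drives an atomic bulk load from CSV spreadsheets through exactly
# the same rule-checked write paths as interactive entry.  Foreign keys
# are resolved against the code table with similar-key detection; any row
# error rolls the entire load back.

LOADER_MODES <- c("individuals_only", "samples_and_final",
                  "samples_raw_and_final", "final_only")

loader_required_keys <- function(mode) {
  switch(mode,
    individuals_only = c("mode", "individuals"),
    samples_and_final = c("mode", "project", "samples"),
    samples_raw_and_final = c("mode", "project", "samples", "raw_dir"),
    final_only = c("mode", "project"))
}

loader_known_keys <- c("mode", "project", "purpose", "id_system",
                       "individuals", "samples", "microsats", "markers",
                       "ploidy", "software", "fasta", "fasta_marker",
                       "raw_dir", "dry_run")

#' Parse a batch-loader configuration file
#'
#' The file is a sequence of `name = value` records (one per line, `#`
#' comments allowed).  Required keys depend on `mode`; for duplicate keys
#' the last value wins (with a warning); unknown keys are reported as
#' warnings but do not fail the parse.
#'
#' @param path Configuration file.
#' @return A `genolims_loader_config` list; parse warnings in attribute
#'   `warnings`.
#' @export
parse_loader_config <- function(path) {
  if (!file.exists(path))
    stop_genolims(paste0("no config file: ", path), "genolims_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list(); warns <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop_genolims(paste0("malformed config record: ", ln),
                    "genolims_config_error")
    key <- m[[2L]]; val <- trimws(m[[3L]])
    if (!is.null(cfg[[key]]))
      warns <- c(warns, paste0("duplicate key '", key, "': last value wins"))
    if (!key %in% loader_known_keys)
      warns <- c(warns, paste0("unknown key '", key, "' ignored"))
    cfg[[key]] <- val
  }
  if (is.null(cfg$mode))
    stop_genolims("config is missing required key 'mode'", "genolims_config_error")
  if (!cfg$mode %in% LOADER_MODES)
    stop_genolims(paste0("invalid mode '", cfg$mode, "' (one of: ",
                         paste(LOADER_MODES, collapse = ", "), ")"),
                  "genolims_config_error")
  missing <- setdiff(loader_required_keys(cfg$mode), names(cfg))
  if (length(missing))
    stop_genolims(paste0("config is missing required key(s): ",
                         paste(missing, collapse = ", ")),
                  "genolims_config_error")
  if (cfg$mode == "final_only" &&
      is.null(cfg$microsats) && is.null(cfg$fasta))
    stop_genolims("final_only mode needs a 'microsats' sheet or a 'fasta' file",
                  "genolims_config_error")
  base <- dirname(path)
  for (key in c("individuals", "samples", "microsats", "fasta", "raw_dir")) {
    if (is.null(cfg[[key]])) next
    p <- cfg[[key]]
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- cfg[[key]] <- file.path(base, p)
    if (!file.exists(p))
      stop_genolims(paste0("config key '", key, "': path does not exist: ", p),
                    "genolims_config_error")
  }
  cfg$id_system <- cfg$id_system %||% "default"
  cfg$purpose <- cfg$purpose %||% "unknown"
  cfg$ploidy <- cfg$ploidy %||% "diploid"
  cfg$dry_run <- isTRUE(tolower(cfg$dry_run %||% "false") %in% c("true", "1", "yes"))
  structure(cfg, class = "genolims_loader_config", warnings = warns)
}

new_load_report <- function() {
  r <- new.env(parent = emptyenv())
  r$inserted <- integer(0)
  r$new_codes <- character(0)
  r$similar_keys <- data.frame(class = character(0), value = character(0),
                               candidate = character(0), distance = integer(0),
                               stringsAsFactors = FALSE)
  r$errors <- character(0)
  r$rolled_back <- FALSE
  r$rows_processed <- 0L
  r
}

finish_report <- function(r) {
  structure(list(inserted = r$inserted, new_codes = r$new_codes,
                 similar_keys = r$similar_keys, errors = r$errors,
                 rolled_back = r$rolled_back,
                 rows_processed = r$rows_processed),
            class = "genolims_load_report")
}

#' @export
print.genolims_load_report <- function(x, ...) {
  cat("<batch load report>", if (x$rolled_back) "ROLLED BACK" else "committed", "\n")
  cat("  rows processed:", x$rows_processed, "\n")
  if (length(x$inserted)) {
    cat("  inserted:\n")
    for (nm in names(x$inserted))
      cat(sprintf("    %-20s %d\n", nm, x$inserted[[nm]]))
  }
  if (length(x$new_codes))
    cat("  new codes:", paste(x$new_codes, collapse = ", "), "\n")
  if (nrow(x$similar_keys)) {
    cat("  similar-key warnings:\n")
    for (i in seq_len(nrow(x$similar_keys)))
      cat(sprintf("    '%s' ~ existing '%s' (%s, distance %d)\n",
                  x$similar_keys$value[i], x$similar_keys$candidate[i],
                  x$similar_keys$class[i], x$similar_keys$distance[i]))
  }
  if (length(x$errors)) cat("  errors:\n", paste0("    ", x$errors, "\n"))
  invisible(x)
}

# Optimal string alignment distance (Levenshtein + adjacent transposition):
# "Holstien" is one edit from "Holstein".  Code lists per class are small,
# so a plain DP is fine.
osa_distance <- function(a, b) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  la <- length(a); lb <- length(b)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la; d[1L, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    cost <- as.integer(a[[i]] != b[[j]])
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + cost)
    if (i > 1L && j > 1L && a[[i]] == b[[j - 1L]] && a[[i - 1L]] == b[[j]])
      d[i + 1L, j + 1L] <- min(d[i + 1L, j + 1L], d[i - 1L, j - 1L] + cost)
  }
  d[la + 1L, lb + 1L]
}

#' Resolve a foreign-key value against the code table
#'
#' An exact case-insensitive match on an existing short name returns the
#' existing code.  Otherwise a new code is created and the class is
#' scanned for similarly spelt keys (edit distance <= 1 after case
#' folding); each near-match is appended to the report as a similar-key
#' warning — new codes are never silently merged into near matches.
#'
#' @param db A database handle.
#' @param class Code class.
#' @param value Text value from a spreadsheet (non-empty).
#' @param report A load report (environment) collecting new codes and
#'   warnings; optional.
#' @return The code id.
#' @export
resolve_code <- function(db, class, value, report = NULL) {
  if (is.null(value) || is.na(value) || !nzchar(trimws(as.character(value))))
    stop_genolims("empty value cannot be resolved to a code",
                  "genolims_invalid_value")
  value <- trimws(as.character(value))
  existing <- list_codes(db, class)
  hit <- which(tolower(existing$short_name) == tolower(value))
  if (length(hit) >= 1L) return(existing$code_id[[hit[[1L]]]])
  dists <- vapply(existing$short_name, function(s)
    osa_distance(tolower(s), tolower(value)), 0L, USE.NAMES = FALSE)
  near <- which(dists <= 1L)
  code <- add_code(db, class, value)
  if (!is.null(report)) {
    report$new_codes <- c(report$new_codes, paste0(class, ":", value))
    for (i in near) {
      report$similar_keys <- rbind(report$similar_keys, data.frame(
        class = class, value = value,
        candidate = existing$short_name[[i]],
        distance = dists[[i]], stringsAsFactors = FALSE))
    }
  }
  code$code_id
}

read_loader_sheet <- function(path, required, sheet_name) {
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop_genolims(sprintf("sheet '%s': missing column(s) %s", sheet_name,
                          paste(missing, collapse = ", ")),
                  "genolims_structural_error")
  tab
}

sheet_cell <- function(tab, col, i) {
  if (!col %in% names(tab)) return("")
  v <- tab[[col]][[i]]
  if (is.na(v)) "" else as.character(v)
}

with_coord <- function(sheet, row, expr) {
  tryCatch(expr, genolims_error = function(e) {
    stop_genolims(sprintf("sheet '%s', row %s: %s", sheet,
                          if (is.na(row)) "-" else row, conditionMessage(e)),
                  "genolims_load_error")
  })
}

# shared by run_load and by the interactive-equivalence oracle in tests:
# register organisms (idempotent) + samples from the samples sheet
load_samples_sheet <- function(db, cfg, tab, report) {
  for (i in seq_len(nrow(tab))) {
    with_coord("samples", i, {
      org <- loader_register_individual(db, cfg, tab, i, report)
      amount <- suppressWarnings(as.numeric(sheet_cell(tab, "amount", i)))
      register_sample(
        db, org, cfg$project,
        material_type = resolve_code(db, "MATERIAL_TYPE",
                                     sheet_cell(tab, "material_type", i), report),
        vessel_type = if (nzchar(sheet_cell(tab, "vessel_type", i)))
          resolve_code(db, "VESSEL_TYPE", sheet_cell(tab, "vessel_type", i),
                       report) else NULL,
        amount = if (is.na(amount)) NULL else amount,
        unit = chr_or_null(sheet_cell(tab, "unit", i)))
      report$rows_processed <- report$rows_processed + 1L
    })
  }
}

loader_register_individual <- function(db, cfg, tab, i, report) {
  register_individual(
    db,
    id_system = if (nzchar(sheet_cell(tab, "id_system", i)))
      sheet_cell(tab, "id_system", i) else cfg$id_system,
    external_id = sheet_cell(tab, "external_id", i),
    species = resolve_code(db, "SPECIES", sheet_cell(tab, "species", i), report),
    breed = if (nzchar(sheet_cell(tab, "breed", i)))
      resolve_code(db, "BREED", sheet_cell(tab, "breed", i), report) else NULL,
    sex = if (nzchar(sheet_cell(tab, "sex", i)))
      resolve_code(db, "SEX", sheet_cell(tab, "sex", i), report) else NULL)
}

loader_ensure_project <- function(db, cfg) {
  r <- dbGetQuery(db$con, "SELECT project_id FROM projects WHERE name = ?",
                  params = list(cfg$project))
  if (nrow(r) == 1L) return(r$project_id)
  add_project(db, cfg$project, purpose = resolve_code(db, "PURPOSE", cfg$purpose))
}

# one PCR per chunk of <= 96 DNAs carrying all loader markers
loader_setup_pcrs <- function(db, dna_ids, markers) {
  for (idx in chunk_index(length(dna_ids), 96L))
    setup_pcr(db, dna_ids[idx], markers)
}

run_load_steps <- function(db, cfg, report) {
  project_exists <- cfg$mode == "final_only"
  if (cfg$mode != "individuals_only") {
    if (project_exists) {
      project_id_for(db, cfg$project)   # must already exist
    } else loader_ensure_project(db, cfg)
  }

  if (!is.null(cfg$individuals)) {
    tab <- read_loader_sheet(cfg$individuals,
                             c("external_id", "species"), "individuals")
    for (i in seq_len(nrow(tab))) {
      with_coord("individuals", i, {
        loader_register_individual(db, cfg, tab, i, report)
        report$rows_processed <- report$rows_processed + 1L
      })
    }
  }
  if (cfg$mode == "individuals_only") return(invisible(NULL))

  new_dna <- integer(0)
  if (!is.null(cfg$samples)) {
    tab <- read_loader_sheet(cfg$samples,
      c("external_id", "species", "material_type", "amount", "unit"), "samples")
    load_samples_sheet(db, cfg, tab, report)
    # 1:1 DNA extraction per freshly loaded sample, in sheet order
    fresh <- dbGetQuery(db$con, sprintf(
      "SELECT s.sample_id FROM samples s
        WHERE s.project_id = %d AND s.sample_id NOT IN
          (SELECT sample_id FROM dna_extraction)
        ORDER BY s.sample_id", project_id_for(db, cfg$project)))$sample_id
    new_dna <- vapply(fresh, function(s) extract_dna(db, s), integer(1))
  }

  markers <- character(0)
  if (!is.null(cfg$markers))
    markers <- trimws(strsplit(cfg$markers, ",", fixed = TRUE)[[1L]])
  if (!is.null(cfg$fasta_marker)) markers <- union(markers, cfg$fasta_marker)
  marker_ids <- vapply(markers, function(m)
    resolve_code(db, "PRIMER", m, report), integer(1))

  needs_pcr <- !is.null(cfg$fasta) && cfg$mode != "final_only"
  if (needs_pcr && length(new_dna))
    loader_setup_pcrs(db, new_dna, marker_ids)

  if (!is.null(cfg$raw_dir)) {
    files <- sort(list.files(cfg$raw_dir, full.names = TRUE))
    for (f in files) with_coord("raw_dir", NA, load_raw_file(db, cfg, f))
  }

  if (!is.null(cfg$microsats)) {
    msat_markers <- trimws(strsplit(cfg$markers %||%
      stop_genolims("'microsats' sheet requires 'markers'",
                    "genolims_config_error"), ",", fixed = TRUE)[[1L]])
    with_coord("microsats", NA, {
      import_microsat_matrix(db, cfg$project, cfg$microsats,
                             markers = vapply(msat_markers, function(m)
                               resolve_code(db, "PRIMER", m, report), integer(1)),
                             ploidy = cfg$ploidy,
                             software = if (!is.null(cfg$software))
                               resolve_code(db, "SOFTWARE", cfg$software, report)
                             else NULL)
    })
  }
  if (!is.null(cfg$fasta)) {
    with_coord("fasta", NA, {
      import_sequences(db, cfg$project, cfg$fasta,
                       marker = resolve_code(db, "PRIMER", cfg$fasta_marker %||%
                         stop_genolims("'fasta' requires 'fasta_marker'",
                                       "genolims_config_error"), report),
                       software = if (!is.null(cfg$software))
                         resolve_code(db, "SOFTWARE", cfg$software, report)
                       else NULL)
    })
  }
  invisible(NULL)
}

# raw files are named <sample external id>.<ext>; each is attached to an
# electrophoresis run of the PCR covering that sample's DNA
load_raw_file <- function(db, cfg, path) {
  key <- sub("\\.[^.]*$", "", basename(path))
  hit <- dbGetQuery(db$con,
    "SELECT a.pcr_id FROM amplified_samples a
      WHERE a.dna_id IN (
        SELECT d.dna_id FROM dna_extraction d
         JOIN samples s ON s.sample_id = d.sample_id
         JOIN transfer t ON t.organism_id = s.organism_id
        WHERE t.external_id = ?)
      ORDER BY a.amplified_id LIMIT 1", params = list(key))
  if (nrow(hit) == 0L)
    stop_genolims(paste0("raw file '", basename(path),
                         "' does not match any loaded sample"),
                  "genolims_unresolved_id")
  run <- dbGetQuery(db$con,
    "SELECT run_id FROM electrophoresis WHERE pcr_id = ? LIMIT 1",
    params = list(hit$pcr_id))
  run_id <- if (nrow(run)) run$run_id
  else record_electrophoresis(db, hit$pcr_id)
  store_blob(db, path, run_id = run_id)
}

#' Execute a batch load
#'
#' Runs the whole migration inside one transaction through the same
#' rule-checked write paths as interactive entry, in a fixed order (codes,
#' contacts, project, organisms, samples, DNA, PCR, electrophoresis, final
#' data) so forward references never occur.  On any error the entire load
#' is rolled back and the database is byte-identical to its pre-load
#' state.  With `dry_run` everything is executed and then rolled back
#' unconditionally, still producing the full report.
#'
#' @param db A database handle.
#' @param config A `genolims_loader_config` from [parse_loader_config()],
#'   or a path to a configuration file.
#' @return A `genolims_load_report`: per-relation inserted counts, new
#'   codes, similar-key warnings, errors, and the rollback flag.
#' @export
run_load <- function(db, config) {
  authz(db, task = "b", action = "write")
  cfg <- if (is.character(config)) parse_loader_config(config) else config
  report <- new_load_report()
  before <- vapply(lims_relations(db), function(r) db_count(db, r), numeric(1))

  capture_inserted <- function() {
    after <- vapply(lims_relations(db), function(r) db_count(db, r), numeric(1))
    d <- after - before
    report$inserted <- as.integer(d[d > 0])
    names(report$inserted) <- names(d)[d > 0]
  }

  outcome <- tryCatch({
    lims_transaction(db, {
      run_load_steps(db, cfg, report)
      capture_inserted()
      if (cfg$dry_run)
        stop(structure(class = c("genolims_dry_run", "error", "condition"),
                       list(message = "dry run", call = NULL)))
    })
    "committed"
  },
  genolims_dry_run = function(e) "dry_run",
  genolims_error = function(e) {
    report$errors <- c(report$errors, conditionMessage(e))
    "error"
  })

  if (outcome != "committed") report$rolled_back <- TRUE
  if (outcome == "error") report$inserted <- integer(0)
  finish_report(report)
}

#' Emit empty loader spreadsheet templates and a config skeleton
#'
#' @param mode One of the four loader modes.
#' @param dir Output directory (created).
#' @return Paths of the written files, invisibly.
#' @export
loader_template <- function(mode, dir) {
  if (!mode %in% LOADER_MODES)
    stop_genolims(paste0("invalid mode: ", mode), "genolims_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, cols) {
    p <- file.path(dir, paste0(name, ".csv"))
    write.csv(setNames(data.frame(matrix(character(0), 0, length(cols))), cols),
              p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (mode == "individuals_only")
    put("individuals", c("id_system", "external_id", "species", "breed", "sex"))
  if (mode %in% c("samples_and_final", "samples_raw_and_final"))
    put("samples", c("id_system", "external_id", "species", "breed", "sex",
                     "material_type", "vessel_type", "amount", "unit"))
  cfgp <- file.path(dir, "load.conf")
  writeLines(c(paste0("mode = ", mode),
               if (mode != "individuals_only") "project = PROJECT_NAME",
               if (mode == "individuals_only")
                 paste0("individuals = ", file.path(dir, "individuals.csv"))
               else if (mode != "final_only")
                 paste0("samples = ", file.path(dir, "samples.csv")),
               "# microsats = genotypes.csv", "# markers = M1,M2",
               "# fasta = sequences.fasta", "# fasta_marker = M1",
               "# dry_run = true"), cfgp)
  invisible(c(paths, cfgp))
}
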