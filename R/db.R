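# Database handle, schema initialisation, transactions and the low-level
# write path.  Every write — interactive or batch — funnels through
# db_insert()/db_update(), which validate against the business-rule set
# before touching the store, inside a transaction.

new_db_handle <- function(con, path, schema, classes) {
  db <- new.env(parent = emptyenv())
  db$con <- con
  db$path <- path
  db$schema <- schema
  db$classes <- classes
  db$session <- NULL
  db$txn_depth <- 0L
  db$matrices <- NULL   # role matrices, loaded lazily (see access layer)
  class(db) <- "genolims_db"
  db
}

#' @export
print.genolims_db <- function(x, ...) {
  cat("<genolims database>\n")
  cat("  file:     ", x$path, "\n", sep = "")
  cat("  relations:", length(x$schema), "\n")
  n <- vapply(names(x$schema), function(r)
    dbGetQuery(x$con, paste0("SELECT COUNT(*) AS n FROM ", r))$n, numeric(1))
  cat("  records:  ", sum(n), "\n")
  if (!is.null(x$session))
    cat("  session:  ", x$session$login, "\n")
  invisible(x)
}

#' Create a new LIMS database
#'
#' Initialises the embedded single-file database: creates all 23 relations
#' of the data model, seeds every code class with a sentinel `unknown`
#' code, and loads the business-rule set that guards all subsequent
#' writes.
#'
#' @param path File path for the SQLite database (created; parent directory
#'   must be writable).
#' @param overwrite Replace an existing database at `path`.  Without this
#'   flag, initialising over an existing schema is an error.
#' @param rules_file,classes_file Optional overrides for the model file and
#'   the code-class seed file.
#' @return A database handle (class `genolims_db`).
#' @examples
#' db <- init_schema(tempfile(fileext = ".db"))
#' length(lims_relations(db))   # 23
#' lims_close(db)
#' @export
init_schema <- function(path, overwrite = FALSE,
                        rules_file = schema_config_path(),
                        classes_file = code_class_path()) {
  if (file.exists(path)) {
    if (!overwrite)
      stop_genolims(paste0("schema exists at '", path,
                           "' (use overwrite = TRUE to replace it)"),
                    "genolims_schema_exists")
    unlink(path)
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop_genolims(paste0("location not writable: ", dir), "genolims_io_error")

  schema <- read_schema_config(rules_file)
  classes <- read_code_classes(classes_file)
  con <- dbConnect(RSQLite::SQLite(), path)
  db <- new_db_handle(con, path, schema, classes)
  for (rel in schema) dbExecute(con, schema_ddl(rel))
  # query-path indexes (indexes are not relations; the model stays 23 tables)
  idx <- c("codes (code_class, short_name)",
           "transfer (organism_id)", "transfer (id_system, external_id)",
           "samples (project_id)", "samples (organism_id)",
           "dna_extraction (dna_id)", "dna_extraction (sample_id)",
           "amplified_samples (dna_id)", "amplified_samples (pcr_id)",
           "pcr_markers (pcr_id)", "sequences (amplified_id)",
           "microsatellites (project_id)", "storage (parent_id)",
           "storage_samples (storage_id)", "storage_samples (item_type, item_id)",
           "blobs (run_id)")
  for (i in seq_along(idx))
    dbExecute(con, sprintf("CREATE INDEX genolims_idx_%02d ON %s", i, idx[[i]]))
  # sentinel code per class so incomplete historical data can always load
  lims_transaction(db, {
    for (cl in classes$class) {
      db_insert(db, "codes", list(code_class = cl, short_name = "unknown",
                                  long_name = "unknown", active = 1L))
    }
  })
  db
}

#' Open an existing LIMS database
#'
#' @param path Path of a database created by [init_schema()].
#' @inheritParams init_schema
#' @return A database handle.
#' @export
lims_open <- function(path, rules_file = schema_config_path(),
                      classes_file = code_class_path()) {
  if (!file.exists(path))
    stop_genolims(paste0("no database at '", path, "'"), "genolims_io_error")
  schema <- read_schema_config(rules_file)
  con <- dbConnect(RSQLite::SQLite(), path)
  present <- dbListTables(con)
  missing <- setdiff(names(schema), present)
  if (length(missing)) {
    dbDisconnect(con)
    stop_genolims(paste0("not a genolims database (missing relations: ",
                         paste(missing, collapse = ", "), ")"),
                  "genolims_io_error")
  }
  new_db_handle(con, path, schema, read_code_classes(classes_file))
}

#' Close a database handle
#' @param db A database handle.
#' @export
lims_close <- function(db) {
  if (!is.null(db$con)) dbDisconnect(db$con)
  db$con <- NULL
  invisible(NULL)
}

#' List the relations of the data model
#' @param db A database handle.
#' @return Character vector of relation names (length 23).
#' @export
lims_relations <- function(db) names(db$schema)

#' The business-rule set
#'
#' Returns the declarative per-relation rules (not-null columns, unique
#' column sets, foreign keys, value types) loaded from the model file.
#' @param db A database handle.
#' @export
business_rules <- function(db) db$schema

# ---- transactions ----------------------------------------------------------

#' Run code inside a database transaction
#'
#' Nested calls use savepoints, so an inner failure rolls back only its own
#' work unless the error propagates.  On error the database is byte-wise
#' unchanged (atomicity of batch operations relies on this).
#'
#' @param db A database handle.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
lims_transaction <- function(db, code) {
  depth <- db$txn_depth
  sp <- paste0("genolims_sp_", depth)
  if (depth == 0L) dbBegin(db$con) else dbExecute(db$con, paste0("SAVEPOINT ", sp))
  db$txn_depth <- depth + 1L
  ok <- FALSE
  on.exit({
    db$txn_depth <- depth
    if (ok) {
      if (depth == 0L) dbCommit(db$con)
      else dbExecute(db$con, paste0("RELEASE ", sp))
    } else {
      if (depth == 0L) {
        dbRollback(db$con)
      } else {
        dbExecute(db$con, paste0("ROLLBACK TO ", sp))
        dbExecute(db$con, paste0("RELEASE ", sp))
      }
    }
  })
  res <- force(code)
  ok <- TRUE
  res
}

# ---- low-level reads -------------------------------------------------------

rel_or_stop <- function(db, relation) {
  rel <- db$schema[[relation]]
  if (is.null(rel))
    stop_genolims(paste0("unknown relation: ", relation), "genolims_unknown_relation")
  rel
}

db_table <- function(db, relation, columns = NULL) {
  rel <- rel_or_stop(db, relation)
  cols <- columns %||% names(rel$columns)
  dbGetQuery(db$con, sprintf("SELECT %s FROM %s ORDER BY %s",
                             paste(cols, collapse = ", "), relation, rel$pk))
}

db_get <- function(db, relation, id) {
  rel <- rel_or_stop(db, relation)
  r <- dbGetQuery(db$con,
                  sprintf("SELECT * FROM %s WHERE %s = ?", relation, rel$pk),
                  params = list(id))
  if (nrow(r) == 0L) NULL else r
}

db_count <- function(db, relation) {
  dbGetQuery(db$con, paste0("SELECT COUNT(*) AS n FROM ", relation))$n
}

db_next_id <- function(db, relation, column = NULL) {
  rel <- rel_or_stop(db, relation)
  column <- column %||% rel$pk
  dbGetQuery(db$con, sprintf("SELECT COALESCE(MAX(%s), 0) + 1 AS n FROM %s",
                             column, relation))$n
}

# ---- low-level writes ------------------------------------------------------

# Insert a batch of records (list of named lists or a data.frame) after
# rule validation; returns the assigned primary keys.
db_insert_many <- function(db, relation, records) {
  rel <- rel_or_stop(db, relation)
  if (is.data.frame(records)) records <- df_to_records(records)
  if (length(records) == 0L) return(integer(0))
  lims_transaction(db, {
    v <- check_rules_batch(db, relation, records)
    if (nrow(v) > 0L) stop_rule_violation(relation, v)
    ids <- db_next_id(db, relation) + seq_along(records) - 1L
    cols <- names(rel$columns)
    data_cols <- setdiff(cols, rel$pk)
    sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", relation,
                   paste(cols, collapse = ", "),
                   paste(rep("?", length(cols)), collapse = ", "))
    params <- c(list(ids), lapply(data_cols, function(cn) {
      col <- rel$columns[[cn]]
      vals <- lapply(records, function(r) sql_value(r[[cn]], col$type))
      if (col$type == "blob") {
        structure(vals, class = "blob")
      } else {
        unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
      }
    }))
    names(params) <- NULL
    dbExecute(db$con, sql, params = params)
    ids
  })
}

db_insert <- function(db, relation, record) {
  db_insert_many(db, relation, list(record))[[1L]]
}

db_update <- function(db, relation, id, values) {
  rel <- rel_or_stop(db, relation)
  cur <- db_get(db, relation, id)
  if (is.null(cur))
    stop_genolims(sprintf("%s: no record with %s = %s", relation, rel$pk, id),
                  "genolims_not_found")
  merged <- df_to_records(cur)[[1L]]
  for (nm in names(values)) merged[[nm]] <- values[[nm]]
  merged[[rel$pk]] <- NULL
  lims_transaction(db, {
    v <- check_rules_batch(db, relation, list(merged), exclude_id = id)
    if (nrow(v) > 0L) stop_rule_violation(relation, v)
    sets <- paste0(names(values), " = ?")
    params <- lapply(names(values), function(cn)
      sql_value(values[[cn]], rel$columns[[cn]]$type) %||% NA)
    dbExecute(db$con,
              sprintf("UPDATE %s SET %s WHERE %s = ?", relation,
                      paste(sets, collapse = ", "), rel$pk),
              params = c(params, list(id)))
  })
  invisible(id)
}

db_delete <- function(db, relation, id) {
  rel <- rel_or_stop(db, relation)
  n <- dbExecute(db$con, sprintf("DELETE FROM %s WHERE %s = ?", relation, rel$pk),
                 params = list(id))
  if (n == 0L)
    stop_genolims(sprintf("%s: no record with %s = %s", relation, rel$pk, id),
                  "genolims_not_found")
  invisible(n)
}

sql_value <- function(x, type) {
  if (is.null(x) || (length(x) == 1L && is.na(x) && type != "blob")) return(NULL)
  switch(type,
    blob = if (is.raw(x)) x else stop("blob column requires a raw vector"),
    flag = as.integer(as.logical(x)),
    integer = as.integer(x),
    id = as.integer(x),
    code = as.integer(x),
    ref = as.integer(x),
    number = as.numeric(x),
    date = as_iso_date(x),
    as.character(x))
}

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- lapply(df, function(col) {
      v <- col[[i]]
      if (length(v) == 1L && is.na(v)) NULL else v
    })
    r[!vapply(r, is.null, TRUE)]
  })
}

# ---- whole-database digests ------------------------------------------------

#' Digest of the full database state
#'
#' A deterministic digest over every relation's content (including blob
#' bytes), used by the atomicity and read-only guarantees: two databases
#' with identical content have identical digests.
#'
#' @param db A database handle.
#' @return A hex digest string.
#' @export
lims_digest <- function(db) {
  state <- lapply(names(db$schema)[order(names(db$schema))], function(rn) {
    tab <- db_table(db, rn)
    # normalise blob columns to checksums for stable hashing
    for (cn in names(tab)) {
      if (inherits(tab[[cn]], "blob") || is.list(tab[[cn]]))
        tab[[cn]] <- vapply(tab[[cn]], function(b)
          if (is.null(b) || length(b) == 0L) "" else md5_raw(b), "")
    }
    tab
  })
  digest::digest(state, algo = "md5")
}
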