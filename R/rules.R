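# The business-rule checker: the meta layer every write passes through.
# Rules come from the model file (see read_schema_config) and are limited
# to not-null, unique, foreign-key and value-type constraints.  Violations
# are reported as data, so callers can render or rethrow them.

empty_violations <- function() {
  data.frame(row = integer(0), rule = character(0), column = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

violation <- function(row, rule, column, message) {
  data.frame(row = row, rule = rule, column = column, message = message,
             stringsAsFactors = FALSE)
}

stop_rule_violation <- function(relation, v) {
  stop_genolims(
    paste0("business-rule violation(s) on '", relation, "': ",
           paste(sprintf("[%s %s.%s] %s", v$rule, relation, v$column, v$message),
                 collapse = "; ")),
    "genolims_rule_violation", data = list(violations = v, relation = relation))
}

#' Validate a record against the business rules of a relation
#'
#' Checks a candidate record against the declarative rule set: not-null
#' columns, value types, unique column sets (against both the record batch
#' and the stored relation) and foreign keys (controlled-vocabulary code
#' classes or relation references).  An empty result means the record may
#' be persisted; all writes in the package call this internally and refuse
#' to persist a record with a non-empty violation list.
#'
#' @param db A database handle.
#' @param relation Relation name.
#' @param record Named list (or one-row data.frame) of column values; the
#'   surrogate primary key is assigned by the store and must be absent.
#' @return A data.frame of violations with columns `rule`, `column`,
#'   `message` (zero rows when valid).
#' @export
check_rules <- function(db, relation, record) {
  if (is.data.frame(record)) record <- df_to_records(record)[[1L]]
  v <- check_rules_batch(db, relation, list(record))
  v[, c("rule", "column", "message")]
}

# Batch version: `records` is a list of named lists.  exclude_id excludes a
# stored row (by primary key) from uniqueness checks, for updates.
check_rules_batch <- function(db, relation, records, exclude_id = NULL) {
  rel <- rel_or_stop(db, relation)
  out <- list(empty_violations())
  cols <- rel$columns
  n <- length(records)

  # column name validity
  for (i in seq_len(n)) {
    unknown <- setdiff(names(records[[i]]), names(cols))
    for (u in unknown)
      out[[length(out) + 1L]] <-
        violation(i, "unknown_column", u, "column not declared for this relation")
  }

  get_col <- function(cn) lapply(records, function(r) scalar_or_na(r[[cn]]))

  for (cn in names(cols)) {
    col <- cols[[cn]]
    if (col$type == "id") next   # assigned by the store
    vals <- get_col(cn)
    present <- !vapply(vals, function(v)
      is.null(v) || (!is.raw(v) && length(v) == 1L && is.na(v)) ||
        (is.character(v) && length(v) == 1L && !nzchar(v)), TRUE)

    if (col$notnull) {
      for (i in which(!present))
        out[[length(out) + 1L]] <-
          violation(i, "not_null", cn, "required value is missing")
    }
    idx <- which(present)
    if (length(idx) == 0L) next
    vv <- vals[idx]

    bad_type <- switch(col$type,
      integer = ,
      code = ,
      ref = !vapply(vv, function(v)
        is.numeric(v) && !is.na(v) && v == round(v), TRUE),
      number = !vapply(vv, function(v) is.numeric(v) && !is.na(v), TRUE),
      flag = !vapply(vv, function(v)
        is.logical(v) || (is.numeric(v) && v %in% c(0, 1)), TRUE),
      date = !vapply(vv, function(v)
        inherits(v, "Date") ||
          (is.character(v) && grepl("^\\d{4}-\\d{2}-\\d{2}$", v)), TRUE),
      blob = !vapply(vv, is.raw, TRUE),
      text = !vapply(vv, function(v) is.atomic(v) && length(v) == 1L, TRUE),
      rep(FALSE, length(vv)))
    for (i in idx[bad_type])
      out[[length(out) + 1L]] <-
        violation(i, "type", cn, paste0("value is not a valid ", col$type))
    ok_idx <- idx[!bad_type]

    # foreign keys
    if (col$type == "code" && length(ok_idx)) {
      ids <- as.integer(unlist(vals[ok_idx]))
      known <- dbGetQuery(db$con,
        "SELECT code_id FROM codes WHERE code_class = ?",
        params = list(col$code_class))$code_id
      for (j in which(!(ids %in% known)))
        out[[length(out) + 1L]] <- violation(ok_idx[j], "foreign_key", cn,
          sprintf("code %d not found in class %s", ids[j], col$code_class))
    }
    if (col$type == "ref" && length(ok_idx)) {
      ids <- as.integer(unlist(vals[ok_idx]))
      known <- dbGetQuery(db$con, sprintf(
        "SELECT DISTINCT %s AS k FROM %s WHERE %s IN (%s)",
        col$ref_col, col$ref_rel, col$ref_col,
        paste(unique(ids), collapse = ",")))$k
      for (j in which(!(ids %in% known)))
        out[[length(out) + 1L]] <- violation(ok_idx[j], "foreign_key", cn,
          sprintf("no %s.%s = %d", col$ref_rel, col$ref_col, ids[j]))
    }
  }

  # uniqueness (NULLs compare equal, so duplicate roots etc. are caught)
  key_of <- function(vals_by_col, i) {
    paste(vapply(vals_by_col, function(v) {
      x <- v[[i]]
      if (is.null(x) || (length(x) == 1L && is.na(x))) "\r<null>" else as.character(x)
    }, ""), collapse = "\r|")
  }
  for (uq in rel$uniques) {
    vals_by_col <- lapply(uq, get_col)
    keys <- vapply(seq_len(n), function(i) key_of(vals_by_col, i), "")
    # within-batch duplicates
    dup <- duplicated(keys)
    # against stored rows
    # prefilter stored rows on the first unique column to avoid full scans
    # on large relations (exact key comparison happens in R below)
    pre <- character(0)
    v1 <- unlist(lapply(vals_by_col[[1L]], function(x)
      if (is.null(x) || (length(x) == 1L && is.na(x))) NA else as.character(x)))
    if (!anyNA(v1)) {
      col1 <- rel$columns[[uq[[1L]]]]
      quoted <- if (col1$type %in% c("integer", "id", "code", "ref", "number",
                                     "flag"))
        unique(v1) else paste0("'", gsub("'", "''", unique(v1)), "'")
      pre <- sprintf("%s IN (%s)", uq[[1L]], paste(quoted, collapse = ","))
    }
    if (!is.null(exclude_id))
      pre <- c(pre, sprintf("%s <> %d", rel$pk, as.integer(exclude_id)))
    where <- if (length(pre)) paste0(" WHERE ", paste(pre, collapse = " AND ")) else ""
    stored <- dbGetQuery(db$con, sprintf("SELECT %s FROM %s%s",
                                         paste(uq, collapse = ", "), relation, where))
    if (nrow(stored)) {
      skeys <- vapply(seq_len(nrow(stored)), function(i)
        paste(vapply(uq, function(cn) {
          x <- stored[[cn]][[i]]
          if (is.na(x)) "\r<null>" else as.character(x)
        }, ""), collapse = "\r|"), "")
      dup <- dup | keys %in% skeys
    }
    for (i in which(dup))
      out[[length(out) + 1L]] <- violation(i, "unique", paste(uq, collapse = ","),
        "duplicate value for unique column set")
  }

  do.call(rbind, out)
}
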