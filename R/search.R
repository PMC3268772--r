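# Criteria-based search over any relation: a conjunction of
# (column, operator, value) criteria with multi-column ordering.

search_operators <- c("equals", "contains", "lt", "gt", "between", "<", ">")

#' Search records of a relation by criteria
#'
#' Returns exactly the records satisfying the conjunction of all criteria,
#' ordered by the sort columns.  Supported operators: `equals`, `contains`
#' (substring), `lt`/`<`, `gt`/`>`, and `between` (inclusive; value of
#' length 2).
#'
#' @param db A database handle.
#' @param relation Relation name.
#' @param criteria List of criteria, each a list/vector of
#'   `(column, operator, value)`; empty list returns every record.
#' @param sort Character vector of columns to order by.
#' @return A data.frame of matching records.
#' @examples
#' db <- init_schema(tempfile(fileext = ".db"))
#' search_records(db, "codes", list(list("code_class", "equals", "SEX")))
#' lims_close(db)
#' @export
search_records <- function(db, relation, criteria = list(), sort = NULL) {
  authz(db, task = "c", action = "read")
  rel <- rel_or_stop(db, relation)
  cols <- names(rel$columns)

  clauses <- character(0); params <- list()
  for (cr in criteria) {
    if (length(cr) < 3L) stop_genolims("criterion must be (column, operator, value)",
                                       "genolims_bad_criterion")
    col <- as.character(cr[[1L]]); op <- as.character(cr[[2L]])
    val <- cr[[3L]]
    if (!col %in% cols)
      stop_genolims(paste0("unknown column: ", relation, ".", col),
                    "genolims_unknown_column")
    if (!op %in% search_operators)
      stop_genolims(paste0("unknown operator: ", op), "genolims_unknown_operator")
    if (op %in% c("lt", "<")) { clauses <- c(clauses, paste0(col, " < ?")); params <- c(params, list(val)) }
    else if (op %in% c("gt", ">")) { clauses <- c(clauses, paste0(col, " > ?")); params <- c(params, list(val)) }
    else if (op == "equals") { clauses <- c(clauses, paste0(col, " = ?")); params <- c(params, list(val)) }
    else if (op == "between") {
      if (length(val) != 2L) stop_genolims("'between' needs a value of length 2",
                                           "genolims_bad_criterion")
      clauses <- c(clauses, paste0(col, " BETWEEN ? AND ?"))
      params <- c(params, list(val[[1L]], val[[2L]]))
    } else if (op == "contains") {
      esc <- gsub("([%_\\\\])", "\\\\\\1", as.character(val))
      clauses <- c(clauses, paste0(col, " LIKE ? ESCAPE '\\'"))
      params <- c(params, list(paste0("%", esc, "%")))
    }
  }
  if (!is.null(sort)) {
    bad <- setdiff(sort, cols)
    if (length(bad))
      stop_genolims(paste0("unknown sort column: ", paste(bad, collapse = ", ")),
                    "genolims_unknown_column")
  }
  sql <- paste0("SELECT * FROM ", relation,
                if (length(clauses)) paste0(" WHERE ", paste(clauses, collapse = " AND ")) else "",
                " ORDER BY ", paste(c(sort, rel$pk), collapse = ", "))
  dbGetQuery(db$con, sql, params = if (length(params)) params else NULL)
}
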