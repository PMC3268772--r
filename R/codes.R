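# Controlled-vocabulary code system: all enumerable foreign keys live in
# the single `codes` relation, grouped by a closed set of classes.

#' Add a code to a controlled-vocabulary class
#'
#' @param db A database handle.
#' @param class One of the code classes (see [read_code_classes()]).
#' @param short_name Short text key, unique within the class.
#' @param long_name Descriptive name.
#' @param description Optional free text.
#' @param active Whether the code is offered for new records.
#' @return Invisibly, the new code as a one-row data.frame.
#' @examples
#' db <- init_schema(tempfile(fileext = ".db"))
#' add_code(db, "SPECIES", "BOS", "Bos taurus")
#' lims_close(db)
#' @export
add_code <- function(db, class, short_name, long_name = short_name,
                     description = NULL, active = TRUE) {
  authz(db, task = "f", action = "write")
  if (!class %in% db$classes$class)
    stop_genolims(paste0("unknown code class: ", class), "genolims_unknown_class")
  id <- db_insert(db, "codes", list(
    code_class = class, short_name = short_name, long_name = long_name,
    description = description, active = active))
  invisible(db_get(db, "codes", id))
}

#' Look up a code by class and short name
#'
#' @inheritParams add_code
#' @param required Error (rather than return `NULL`) when absent.
#' @return One-row data.frame, or `NULL`.
#' @export
get_code <- function(db, class, short_name, required = FALSE) {
  r <- dbGetQuery(db$con,
    "SELECT * FROM codes WHERE code_class = ? AND short_name = ?",
    params = list(class, short_name))
  if (nrow(r) == 0L) {
    if (required)
      stop_genolims(sprintf("no code '%s' in class %s", short_name, class),
                    "genolims_unknown_code")
    return(NULL)
  }
  r
}

#' List codes, optionally restricted to one class
#' @inheritParams add_code
#' @param class Optional class filter.
#' @export
list_codes <- function(db, class = NULL) {
  authz(db, task = "c", action = "read")
  if (is.null(class)) db_table(db, "codes")
  else dbGetQuery(db$con,
    "SELECT * FROM codes WHERE code_class = ? ORDER BY code_id",
    params = list(class))
}

# internal: accept a code id, a short name, or NULL -> code_id (or NA)
code_id_for <- function(db, class, value, required = TRUE) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(NA_integer_)
  if (is.numeric(value)) return(as.integer(value))
  r <- get_code(db, class, as.character(value), required = required)
  if (is.null(r)) NA_integer_ else r$code_id
}

code_short <- function(db, code_id) {
  if (is.null(code_id) || length(code_id) == 0L) return(character(0))
  out <- rep(NA_character_, length(code_id))
  ok <- !is.na(code_id)
  if (any(ok)) {
    tab <- dbGetQuery(db$con, "SELECT code_id, short_name FROM codes")
    out[ok] <- tab$short_name[match(code_id[ok], tab$code_id)]
  }
  out
}
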