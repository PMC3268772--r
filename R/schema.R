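# Parsing of the plain-text model file (relations + business rules) and the
# code-class seed file.  The parsed structure is the BusinessRuleSet used by
# check_rules(): every relation has an entry listing not-null columns,
# unique column sets, foreign-key columns (code-class or relation targets)
# and value types.

schema_config_path <- function() {
  system.file("extdata", "schema_rules.txt", package = "genolims", mustWork = TRUE)
}

code_class_path <- function() {
  system.file("extdata", "code_classes.txt", package = "genolims", mustWork = TRUE)
}

#' Read the code-class seed file
#'
#' Returns the closed enumeration of controlled-vocabulary classes (14 by
#' default) used by the `codes` relation.
#'
#' @param path Seed file; defaults to the file shipped with the package.
#' @return A data.frame with columns `class` and `description`.
#' @export
read_code_classes <- function(path = code_class_path()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    class = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Read the relational model / business-rule file
#'
#' Parses the declarative model file into the rule set that guards every
#' write ([check_rules()]).  The rule vocabulary is restricted to not-null,
#' unique, foreign-key (code class or relation column) and value-type
#' constraints.
#'
#' @param path Model file; defaults to the file shipped with the package.
#' @return A named list of relation descriptors (columns, types, rules).
#' @export
read_schema_config <- function(path = schema_config_path()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  rels <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) rels[[cur$name]] <<- cur

  for (ln in lines) {
    toks <- strsplit(ln, "\\s+")[[1L]]
    kw <- toks[[1L]]
    if (kw == "relation") {
      flush()
      cur <- list(name = toks[[2L]], columns = list(), pk = NULL, uniques = list())
    } else if (kw == "column") {
      cn <- toks[[2L]]; ty <- toks[[3L]]
      col <- list(name = cn, type = ty, notnull = "notnull" %in% toks[-(1:3)],
                  code_class = NULL, ref_rel = NULL, ref_col = NULL)
      if (ty == "id") {
        col$type <- "id"; col$notnull <- TRUE
        cur$pk <- cn
      } else if (startsWith(ty, "code:")) {
        col$type <- "code"
        col$code_class <- sub("^code:", "", ty)
      } else if (startsWith(ty, "ref:")) {
        col$type <- "ref"
        tgt <- strsplit(sub("^ref:", "", ty), ".", fixed = TRUE)[[1L]]
        col$ref_rel <- tgt[[1L]]; col$ref_col <- tgt[[2L]]
      }
      cur$columns[[cn]] <- col
    } else if (kw == "unique") {
      cur$uniques <- c(cur$uniques, list(strsplit(toks[[2L]], ",", fixed = TRUE)[[1L]]))
    } else {
      stop("unknown directive in model file: ", ln, call. = FALSE)
    }
  }
  flush()

  # closure check: every foreign-key rule must name an existing target
  for (r in rels) {
    for (col in r$columns) {
      if (identical(col$type, "ref")) {
        tr <- rels[[col$ref_rel]]
        if (is.null(tr) || is.null(tr$columns[[col$ref_col]]))
          stop(sprintf("model file: %s.%s references unknown %s.%s",
                       r$name, col$name, col$ref_rel, col$ref_col), call. = FALSE)
      }
    }
  }
  rels
}

# SQLite storage class per rule type
sql_type_for <- function(type) {
  switch(type,
    id = "INTEGER PRIMARY KEY",
    integer = "INTEGER", code = "INTEGER", ref = "INTEGER", flag = "INTEGER",
    number = "REAL",
    blob = "BLOB",
    "TEXT")
}

schema_ddl <- function(rel) {
  cols <- vapply(rel$columns, function(col)
    paste(col$name, sql_type_for(col$type)), "")
  sprintf("CREATE TABLE %s (%s)", rel$name, paste(cols, collapse = ", "))
}
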