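# Shared fixtures and independent oracles.  Parsers and evaluators here
# are written against the published grammars / definitions, never by
# calling the package's own writer or checker code paths.

tmp_db <- function(..., envir = parent.frame()) {
  path <- tempfile(fileext = ".db")
  db <- init_schema(path, ...)
  withr::defer(lims_close(db), envir = envir)
  db
}

# minimal populated fixture: codes, storage chain, project, organism, sample
basic_fixture <- function(envir = parent.frame()) {
  db <- tmp_db(envir = envir)
  add_code(db, "SPECIES", "BOS", "Bos taurus")
  add_code(db, "BREED", "HOLSTEIN", "Holstein")
  add_code(db, "SEX", "F", "female")
  add_code(db, "SEX", "M", "male")
  add_code(db, "MATERIAL_TYPE", "BLOOD", "whole blood")
  add_code(db, "VESSEL_TYPE", "VIAL", "cryo vial")
  add_code(db, "PRIMER", "MK01", "marker 1")
  add_code(db, "PRIMER", "MK02", "marker 2")
  add_code(db, "SOFTWARE", "SEQTOOL", "analysis tool")
  nodes <- list()
  nodes$lab <- add_storage_node(db, "Lab")
  nodes$freezer <- add_storage_node(db, "Freezer", nodes$lab)
  nodes$shelf <- add_storage_node(db, "Shelf", nodes$freezer)
  nodes$rack <- add_storage_node(db, "Rack", nodes$shelf)
  nodes$box <- add_storage_node(db, "Box", nodes$rack)
  proj <- add_project(db, "P1", "unknown")
  org <- register_individual(db, "tag", "DE-0001", "BOS",
                             breed = "HOLSTEIN", sex = "F")
  smp <- register_sample(db, org, proj, "BLOOD", "VIAL", 5, "ml")
  list(db = db, nodes = nodes, proj = proj, org = org, smp = smp)
}

random_binary_file <- function(n = 1024L) {
  f <- tempfile()
  writeBin(as.raw(sample(0:255, n, replace = TRUE)), f)
  f
}

# ---- independent format parsers (oracles for the exporters) ---------------

# FASTA, written from the grammar: '>' header, sequence lines concatenated
oracle_parse_fasta <- function(lines) {
  heads <- grep("^>", lines)
  ends <- c(heads[-1L] - 1L, length(lines))
  stats::setNames(
    vapply(seq_along(heads), function(i)
      paste(lines[(heads[i] + 1L):ends[i]], collapse = ""), ""),
    sub("^>", "", vapply(strsplit(lines[heads], "\\s+"), `[[`, "", 1L)))
}

# MEGA: '#mega' header, '!' command lines, '#name' then sequence lines
oracle_parse_mega <- function(lines) {
  stopifnot(grepl("^#mega", lines[[1L]], ignore.case = TRUE))
  body <- lines[-1L]
  body <- body[!grepl("^!", body) & nzchar(body)]
  heads <- grep("^#", body)
  ends <- c(heads[-1L] - 1L, length(body))
  stats::setNames(
    vapply(seq_along(heads), function(i)
      paste(body[(heads[i] + 1L):ends[i]], collapse = ""), ""),
    sub("^#", "", body[heads]))
}

# Stockholm: '# STOCKHOLM', 'name seq' lines, '//' terminator
oracle_parse_stockholm <- function(lines) {
  stopifnot(grepl("^# STOCKHOLM", lines[[1L]]))
  body <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  out <- stats::setNames(vapply(parts, `[[`, "", 2L),
                         vapply(parts, `[[`, "", 1L))
  tapply(out, names(out), paste, collapse = "")[unique(names(out))]
}

# blocked 'name seq' formats (PSI-BLAST style): concatenate per name
oracle_parse_blocked <- function(lines) {
  body <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[[`, "", 1L)
  sq <- vapply(parts, function(p) paste(p[-1L], collapse = ""), "")
  vapply(split(sq, factor(nm, levels = unique(nm))), paste, "", collapse = "")
}

# GCG MSF: header up to '//', then blocked 'name seq' lines
oracle_parse_msf <- function(lines) {
  stopifnot(any(grepl("MSF:", lines)))
  sep <- which(trimws(lines) == "//")[1L]
  oracle_parse_blocked(lines[(sep + 1L):length(lines)])
}

# independent edit distance (optimal string alignment: substitutions,
# indels and adjacent transpositions), memoised recursion as the oracle
# for resolve_code's similar-key scan
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- as.integer(a[[i]] != b[[j]])
    best <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
                rec(i - 1L, j - 1L) + cost)
    if (i > 1L && j > 1L && a[[i]] == b[[j - 1L]] && a[[i - 1L]] == b[[j]])
      best <- min(best, rec(i - 2L, j - 2L) + cost)
    memo[[key]] <- best
    best
  }
  rec(length(a), length(b))
}

# brute-force business-rule evaluator: re-implements the four rule kinds
# directly over the declared rule set and full table scans
oracle_check_rules <- function(db, relation, record) {
  rules <- business_rules(db)[[relation]]
  out <- character(0)
  tab <- search_records(db, relation)
  is_missing <- function(v) is.null(v) ||
    (length(v) == 1L && !is.raw(v) && is.na(v)) ||
    (is.character(v) && length(v) == 1L && !nzchar(v))
  for (col in rules$columns) {
    v <- record[[col$name]]
    if (col$type == "id") next
    if (col$notnull && is_missing(v)) out <- c(out, paste("not_null", col$name))
    if (is_missing(v)) next
    if (col$type == "code") {
      codes <- search_records(db, "codes",
        list(list("code_class", "equals", col$code_class)))
      if (!as.integer(v) %in% codes$code_id)
        out <- c(out, paste("foreign_key", col$name))
    }
    if (col$type == "ref") {
      tgt <- search_records(db, col$ref_rel)
      if (!as.integer(v) %in% tgt[[col$ref_col]])
        out <- c(out, paste("foreign_key", col$name))
    }
  }
  for (uq in rules$uniques) {
    key <- paste(vapply(uq, function(cn) {
      v <- record[[cn]]
      if (is_missing(v)) "<null>" else as.character(v)
    }, ""), collapse = "|")
    if (nrow(tab)) {
      stored <- vapply(seq_len(nrow(tab)), function(i)
        paste(vapply(uq, function(cn) {
          v <- tab[[cn]][[i]]
          if (is.na(v)) "<null>" else as.character(v)
        }, ""), collapse = "|"), "")
      if (key %in% stored) out <- c(out, paste("unique", paste(uq, collapse = ",")))
    }
  }
  sort(out)
}
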