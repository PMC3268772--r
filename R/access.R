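# Dual role model: each account holds exactly one system role (SR, gating
# functionality: seven tasks a-g) and one database role (DR, gating data
# actions: read/write/delete/manage_user).  Both matrices are plain-text
# data files, so authorization outcomes can be changed without rebuilding.

system_tasks <- letters[1:7]
data_actions <- c("read", "write", "delete", "manage_user")

default_matrix_file <- function(which) {
  system.file("extdata", paste0("roles_", which, ".txt"),
              package = "genolims", mustWork = TRUE)
}

read_role_matrix <- function(path, valid_entries) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    role <- trimws(parts[[1L]])
    rights <- strsplit(trimws(parts[[2L]]), "\\s+")[[1L]]
    bad <- setdiff(rights, valid_entries)
    if (length(bad))
      stop("invalid entries in role matrix ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    out[[role]] <- rights
  }
  out
}

load_matrices <- function(db) {
  if (is.null(db$matrices)) {
    db$matrices <- list(
      system = read_role_matrix(db$sr_file %||% default_matrix_file("system"),
                                system_tasks),
      database = read_role_matrix(db$dr_file %||% default_matrix_file("database"),
                                  data_actions))
  }
  db$matrices
}

#' The system-role matrix (roles x permitted tasks a-g)
#' @param db A database handle.
#' @export
system_role_matrix <- function(db) load_matrices(db)$system

#' The database-role matrix (roles x permitted data actions)
#' @param db A database handle.
#' @export
database_role_matrix <- function(db) load_matrices(db)$database

#' Point a database at alternative role-matrix files
#'
#' Role matrices are data, not code: editing (or swapping) the matrix files
#' changes authorization outcomes without rebuilding the package.
#'
#' @param db A database handle.
#' @param system_file,database_file Paths of replacement matrix files.
#' @export
lims_set_role_matrices <- function(db, system_file = NULL, database_file = NULL) {
  if (!is.null(system_file)) db$sr_file <- system_file
  if (!is.null(database_file)) db$dr_file <- database_file
  db$matrices <- NULL
  invisible(db)
}

#' Create a user account
#'
#' Credentials are stored as salted SHA-256 digests; no plaintext secret is
#' ever persisted.  Each account carries exactly one system role and one
#' database role.
#'
#' @param db A database handle.
#' @param login Unique login name.
#' @param secret Password.
#' @param system_role One of `user_administrator`, `lab_manager`,
#'   `scientist`, `visitor`.
#' @param db_role One of `read`, `write`, `delete`, `manage_user`,
#'   `full_right`.
#' @param contact_id Optional contact record of the person.
#' @param active Whether the account can authenticate.
#' @return The user id, invisibly.
#' @export
add_user <- function(db, login, secret, system_role, db_role,
                     contact_id = NULL, active = TRUE) {
  authz(db, task = "a", action = "manage_user")
  m <- load_matrices(db)
  if (!system_role %in% names(m$system))
    stop_genolims(paste0("unknown system role: ", system_role), "genolims_bad_role")
  if (!db_role %in% names(m$database))
    stop_genolims(paste0("unknown database role: ", db_role), "genolims_bad_role")
  salt <- paste(sprintf("%02x", sample.int(256L, 8L, replace = TRUE) - 1L),
                collapse = "")
  lims_transaction(db, {
    uid <- db_insert(db, "users", list(
      login = login, pw_salt = salt,
      pw_hash = digest::digest(paste0(salt, secret), algo = "sha256",
                               serialize = FALSE),
      contact_id = contact_id, active = active))
    db_insert(db, "user_roles", list(user_id = uid, system_role = system_role,
                                     db_role = db_role))
    invisible(uid)
  })
}

#' Authenticate a user
#'
#' Succeeds only for an active account whose salted credential digest
#' matches; every failure mode (unknown login, wrong secret, deactivated
#' account) raises the same indistinguishable error.
#'
#' @param db A database handle.
#' @param login,secret Credentials.
#' @return A session object (class `genolims_session`) bound to the
#'   account's system and database roles.
#' @export
authenticate <- function(db, login, secret) {
  refuse <- function() stop_genolims("authentication failed", "genolims_auth_failed")
  u <- dbGetQuery(db$con, "SELECT * FROM users WHERE login = ?",
                  params = list(login))
  if (nrow(u) != 1L) refuse()
  hash <- digest::digest(paste0(u$pw_salt, secret), algo = "sha256",
                         serialize = FALSE)
  if (!identical(hash, u$pw_hash) || !isTRUE(u$active == 1L)) refuse()
  r <- dbGetQuery(db$con, "SELECT * FROM user_roles WHERE user_id = ?",
                  params = list(u$user_id))
  if (nrow(r) != 1L) refuse()
  structure(list(user_id = u$user_id, login = login,
                 system_role = r$system_role, db_role = r$db_role,
                 matrices = load_matrices(db)),
            class = "genolims_session")
}

#' @export
print.genolims_session <- function(x, ...) {
  cat(sprintf("<genolims session: %s (SR: %s, DR: %s)>\n",
              x$login, x$system_role, x$db_role))
  invisible(x)
}

#' Check whether a session permits an action
#'
#' System tasks (letters `a`-`g`) are checked against the system-role
#' matrix, data actions (`read`, `write`, `delete`, `manage_user`) against
#' the database-role matrix.  Deny wins whenever the role row lacks the
#' action.
#'
#' @param session A session from [authenticate()].
#' @param action A system task letter or a data action name.
#' @param target Unused (reserved; per-object ACLs are out of scope).
#' @return `TRUE` (allow) or `FALSE` (deny).
#' @export
authorize <- function(session, action, target = NULL) {
  if (!inherits(session, "genolims_session"))
    stop_genolims("invalid session", "genolims_auth_failed")
  if (action %in% system_tasks)
    return(action %in% (session$matrices$system[[session$system_role]] %||% character(0)))
  if (action %in% data_actions)
    return(action %in% (session$matrices$database[[session$db_role]] %||% character(0)))
  stop_genolims(paste0("unknown action: ", action), "genolims_bad_action")
}

#' Bind a session to a database handle
#'
#' Once bound, every library entry point checks the session's roles before
#' acting (mutators require the matching system task and a data action;
#' reads require task `c`/`d`/`e` and action `read`).  A handle without a
#' session runs unrestricted (embedded/library mode).
#'
#' @param db A database handle.
#' @param login,secret Credentials, passed to [authenticate()].
#' @return The session, invisibly.
#' @export
lims_login <- function(db, login, secret) {
  db$session <- NULL   # authenticate unrestricted
  s <- authenticate(db, login, secret)
  db$session <- s
  invisible(s)
}

#' Drop the session bound to a handle
#' @param db A database handle.
#' @export
lims_logout <- function(db) {
  db$session <- NULL
  invisible(NULL)
}

#' Deactivate a user account
#' @param db A database handle.
#' @param login Login name.
#' @export
deactivate_user <- function(db, login) {
  authz(db, task = "a", action = "manage_user")
  u <- dbGetQuery(db$con, "SELECT user_id FROM users WHERE login = ?",
                  params = list(login))
  if (nrow(u) != 1L)
    stop_genolims(paste0("no user: ", login), "genolims_not_found")
  db_update(db, "users", u$user_id, list(active = FALSE))
}

# internal guard called at the top of every public entry point
authz <- function(db, task = NULL, action = NULL) {
  s <- db$session
  if (is.null(s)) return(invisible(TRUE))
  if (!is.null(task) && !authorize(s, task))
    stop_genolims(sprintf("access denied: role '%s' lacks system task '%s'",
                          s$system_role, task), "genolims_access_denied")
  if (!is.null(action) && !authorize(s, action))
    stop_genolims(sprintf("access denied: role '%s' lacks data action '%s'",
                          s$db_role, action), "genolims_access_denied")
  invisible(TRUE)
}
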