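# Raw files (gel images, chromatograms, archives) are stored as opaque
# binary blobs in the single `blobs` relation, checksum-verified on every
# read; the storage is format-agnostic by design.

#' Store a file as a binary blob
#'
#' Reads the file byte-exactly, records an MD5 checksum (algorithm name
#' stored alongside) and persists the bytes.  Storing the same file twice
#' yields distinct blobs with equal checksums.
#'
#' @param db A database handle.
#' @param file Path of the file to ingest.
#' @param mimetype Optional `MIMETYPE` code (id or short name).
#' @param run_id Optional electrophoresis run the file belongs to.
#' @return The blob id (integer).
#' @export
store_blob <- function(db, file, mimetype = NULL, run_id = NULL) {
  authz(db, task = "b", action = "write")
  if (!is_scalar_chr(file) || !file.exists(file) || dir.exists(file) ||
      file.access(file, 4L) != 0L)
    stop_genolims(paste0("unreadable file: ", file), "genolims_io_error")
  bytes <- readBin(file, "raw", n = file.size(file))
  store_blob_raw(db, bytes, filename = basename(file),
                 mimetype = mimetype, run_id = run_id)
}

# internal: store in-memory bytes
store_blob_raw <- function(db, bytes, filename = NULL, mimetype = NULL,
                           run_id = NULL) {
  stopifnot(is.raw(bytes))
  db_insert(db, "blobs", list(
    filename = filename,
    mimetype_id = code_id_for(db, "MIMETYPE", mimetype),
    content = bytes,
    checksum = md5_raw(bytes),
    checksum_algo = "md5",
    size = length(bytes),
    run_id = run_id))
}

#' Retrieve blob content
#'
#' Returns the stored bytes after verifying them against the recorded
#' checksum; a mismatch (store corruption) is an error.
#'
#' @param db A database handle.
#' @param blob_id Blob id.
#' @return A raw vector.
#' @export
retrieve_blob <- function(db, blob_id) {
  authz(db, task = "c", action = "read")
  r <- db_get(db, "blobs", blob_id)
  if (is.null(r))
    stop_genolims(paste0("no blob with id ", blob_id), "genolims_not_found")
  bytes <- r$content[[1L]]
  if (is.null(bytes)) bytes <- raw(0)
  if (!identical(md5_raw(bytes), r$checksum))
    stop_genolims(paste0("blob ", blob_id, " failed checksum verification"),
                  "genolims_checksum_mismatch")
  bytes
}

#' Blob metadata (filename, checksum, size) without the content
#' @inheritParams retrieve_blob
#' @export
blob_info <- function(db, blob_id) {
  authz(db, task = "c", action = "read")
  r <- db_get(db, "blobs", blob_id)
  if (is.null(r))
    stop_genolims(paste0("no blob with id ", blob_id), "genolims_not_found")
  r[, setdiff(names(r), "content")]
}
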