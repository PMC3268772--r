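# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# NA-safe scalar from a possibly NULL / empty value
scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) NA
  else x[[1L]]
}

chr_or_null <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(as.character(x))) NULL
  else as.character(x)
}

# ISO date validation; dates are persisted as "YYYY-MM-DD" text
as_iso_date <- function(x, what = "date") {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return(NA_character_)
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  x <- as.character(x)
  bad <- !is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(bad)) {
    stop(sprintf("invalid %s (expected YYYY-MM-DD): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

md5_raw <- function(bytes) digest::digest(bytes, algo = "md5", serialize = FALSE)

stop_genolims <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "genolims_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

# deterministic RNG scope: runs expr with the given seed, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

chunk_index <- function(n, size) split(seq_len(n), ceiling(seq_len(n) / size))

wrap_fixed <- function(s, width) {
  if (nchar(s) == 0L) return(character(0))
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}
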