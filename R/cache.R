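#' @title Timestamped file cache
#' @description
#' Query results are cached in plain text files, one per key, so that
#' rebuilding the overview does not flood providers with redundant
#' requests. Each file's first line is an ISO-8601 timestamp; the rest is
#' the payload, so entries stay human-inspectable. An entry is fresh while
#' its age is within the configured interval (default 7 days after the
#' last query to the provider); renewing a key forces the next lookup to
#' miss. Time is always passed in (`now`), never read from the wall
#' clock, so expiry is deterministic and testable.
#' @name cache
NULL

#' Open (and create) a file cache directory
#'
#' @param dir directory path; created if missing
#' @return object of class `bcp_cache`
#' @export
file_cache <- function(dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create cache directory: ", dir, call. = FALSE)
  structure(list(dir = dir), class = "bcp_cache")
}

#' Build a cache key
#'
#' Digest of (endpoint url, operation, concept, serialized filter), so
#' fragment sources sharing one access point cache independently.
#'
#' @param url endpoint url
#' @param operation operation name (e.g. `count`, `stats`, `capabilities`)
#' @param concept optional concept path
#' @param filter optional `bcp_filter`
#' @return character key
#' @export
cache_key <- function(url, operation, concept = NULL, filter = NULL) {
  digest::digest(paste(url, operation, concept %||% "",
                       if (!is.null(filter)) serialize_filter(filter) else "",
                       sep = "\r"), algo = "sha1")
}

cache_file <- function(cache, key) file.path(cache$dir, paste0(key, ".cache"))

#' Cache lookup
#'
#' @param cache a [file_cache()]
#' @param key a [cache_key()]
#' @param now current instant (`POSIXct`)
#' @param interval_days freshness window in days (> 0)
#' @return the cached payload text, or `NULL` on a miss
#' @export
cache_get <- function(cache, key, now, interval_days = 7) {
  stopifnot(interval_days > 0)
  f <- cache_file(cache, key)
  if (!file.exists(f)) return(NULL)
  lines <- tryCatch(readLines(f, encoding = "UTF-8", warn = FALSE),
                    error = function(e) NULL)
  if (is.null(lines) || !length(lines)) {
    warning("corrupt cache entry treated as miss: ", f, call. = FALSE)
    return(NULL)
  }
  ts <- tryCatch(as.POSIXct(lines[1], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 error = function(e) NA)
  if (is.na(ts)) {
    warning("corrupt cache timestamp treated as miss: ", f, call. = FALSE)
    return(NULL)
  }
  age_days <- as.numeric(difftime(now, ts, units = "days"))
  if (age_days > interval_days || age_days < 0) return(NULL)
  paste(lines[-1], collapse = "\n")
}

#' Store a payload
#'
#' Writes atomically (temp file + rename): concurrent writers of the same
#' key end last-writer-wins, never a torn file.
#'
#' @inheritParams cache_get
#' @param payload text to store
#' @return the key, invisibly
#' @export
cache_put <- function(cache, key, payload, now) {
  f <- cache_file(cache, key)
  tmp <- tempfile(pattern = paste0(key, "-"), tmpdir = cache$dir)
  ok <- tryCatch({
    writeLines(c(format(now, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), payload),
               tmp, useBytes = FALSE)
    file.rename(tmp, f)
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!isTRUE(ok)) {
    unlink(tmp)
    stop("cannot write cache entry ", f, call. = FALSE)
  }
  invisible(key)
}

#' Force-invalidate a key
#'
#' The manual "renew" action: guarantees the next [cache_get()] on the key
#' is a miss (and the result is therefore re-fetched).
#'
#' @inheritParams cache_get
#' @return invisibly, `TRUE` if an entry existed
#' @export
cache_renew <- function(cache, key) {
  f <- cache_file(cache, key)
  existed <- file.exists(f)
  unlink(f)
  invisible(existed)
}

#' Drop every entry
#'
#' @inheritParams cache_get
#' @return number of entries removed, invisibly
#' @export
cache_clear <- function(cache) {
  files <- list.files(cache$dir, pattern = "\\.cache$", full.names = TRUE)
  unlink(files)
  invisible(length(files))
}

# memoise a computation through the cache; payload is JSON text
with_cache <- function(cache, key, now, interval_days, compute) {
  if (is.null(cache)) return(compute())
  hit <- cache_get(cache, key, now, interval_days)
  if (!is.null(hit)) return(jsonlite::fromJSON(hit, simplifyVector = FALSE))
  value <- compute()
  cache_put(cache, key,
            jsonlite::toJSON(value, auto_unbox = TRUE, null = "null",
                             digits = NA),
            now)
  value
}
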