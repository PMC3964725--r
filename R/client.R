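#' @title Endpoint client
#' @description
#' Issues capabilities/search/scan requests against an access point through
#' an injectable transport, pages through results, and derives the counting
#' statistics the monitor and mapping checker display. A transport is any
#' `function(url, request_text)` returning response document text; see
#' [mock_transport()] for the in-process transport over synthetic
#' providers and [http_transport()] for live endpoints.
#' @name client
NULL

#' Describe an access point
#'
#' @param url access-point URI (e.g. a provider wrapper CGI with a `dsa`
#'   parameter)
#' @param default_filter optional filter combined (AND) with every request
#'   filter; lets one physical source serve several logical fragments
#' @param timeout_s request timeout in seconds
#' @param retries additional attempts after a failed request (0-5)
#' @return object of class `bcp_endpoint`
#' @export
endpoint <- function(url, default_filter = NULL, timeout_s = 30, retries = 2) {
  if (!is.character(url) || length(url) != 1L || !nzchar(url))
    stop("endpoint url must be a non-empty string", call. = FALSE)
  if (retries < 0 || retries > 5)
    stop("retries must be between 0 and 5", call. = FALSE)
  if (timeout_s <= 0) stop("timeout_s must be positive", call. = FALSE)
  if (!is.null(default_filter) && !inherits(default_filter, "bcp_filter"))
    stop("default_filter must be a bcp_filter", call. = FALSE)
  structure(list(url = url, default_filter = default_filter,
                 timeout_s = timeout_s, retries = as.integer(retries)),
            class = "bcp_endpoint")
}

#' @export
print.bcp_endpoint <- function(x, ...) {
  cat("<endpoint>", x$url, "\n")
  if (!is.null(x$default_filter))
    cat("  fragment filter:", filter_to_text(x$default_filter), "\n")
  invisible(x)
}

#' Per-concept counting statistics
#'
#' `total` counts delivered value *occurrences* (a record carrying three
#' values of a multi-valued concept, e.g. three multimedia FileURIs,
#' contributes three); `distinct` counts unique delivered values;
#' `dropped` counts occurrences the provider removed before serving
#' (reported through drop-report diagnostics). `distinct <= total` always.
#'
#' @param concept concept path
#' @param total,distinct,dropped non-negative integers
#' @return object of class `concept_stats`
#' @export
concept_stats_row <- function(concept, total, distinct, dropped) {
  total <- as.integer(total); distinct <- as.integer(distinct)
  dropped <- as.integer(dropped)
  if (any(c(total, distinct, dropped) < 0L))
    stop("counts must be non-negative", call. = FALSE)
  if (distinct > total) stop("distinct cannot exceed total", call. = FALSE)
  structure(list(concept = concept, total = total, distinct = distinct,
                 dropped = dropped), class = "concept_stats")
}

#' @export
print.concept_stats <- function(x, ...) {
  cat(sprintf("<concept stats> %s: total %d, distinct %d, dropped %d\n",
              x$concept, x$total, x$distinct, x$dropped))
  invisible(x)
}

#' In-process transport over synthetic providers
#'
#' @param providers named list mapping endpoint url -> `synthetic_provider`
#' @param down character vector of urls that should fail (fault injection)
#' @return a transport function `function(url, request_text)`
#' @export
mock_transport <- function(providers, down = character(0)) {
  force(providers); force(down)
  function(url, request_text) {
    if (url %in% down || is.null(providers[[url]]))
      stop(transport_error(url, "connection refused"))
    build_response(handle_request(providers[[url]], parse_request(request_text)))
  }
}

#' Live HTTP transport
#'
#' Issues the request document as a GET query parameter against the access
#' point, the convention provider wrappers accept. Requires network access;
#' all tests use [mock_transport()] instead.
#'
#' @return a transport function
#' @export
http_transport <- function() {
  function(url, request_text) {
    sep <- if (grepl("?", url, fixed = TRUE)) "&" else "?"
    full <- paste0(url, sep, "query=", utils::URLencode(request_text,
                                                        reserved = TRUE))
    con <- url(full, open = "rb")
    on.exit(close(con))
    paste(readLines(con, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
}

transport_error <- function(url, msg) {
  structure(class = c("bcp_transport_error", "error", "condition"),
            list(message = paste0("transport failure for ", url, ": ", msg),
                 call = NULL, url = url))
}

endpoint_unreachable_error <- function(url, attempts) {
  structure(class = c("bcp_unreachable_error", "error", "condition"),
            list(message = sprintf("endpoint unreachable after %d attempt(s): %s",
                                   attempts, url),
                 call = NULL, url = url, attempts = attempts))
}

# issue one request with retry; returns parsed bcp_response
issue <- function(e, transport, req) {
  attempts <- e$retries + 1L
  for (i in seq_len(attempts)) {
    out <- tryCatch(transport(e$url, build_request(req)),
                    bcp_transport_error = function(cond) cond,
                    error = function(cond) cond)
    if (!inherits(out, "condition")) return(parse_response(out))
  }
  stop(endpoint_unreachable_error(e$url, attempts))
}

combine_filters <- function(e, f) {
  if (is.null(e$default_filter)) f
  else if (is.null(f)) e$default_filter
  else flt_and(e$default_filter, f)
}

#' Fetch a source's capabilities
#'
#' @param e a [endpoint()]
#' @param transport a transport function
#' @return a [capabilities_report()] listing every mapped concept with its
#'   searchable flag and declared data type
#' @export
fetch_capabilities <- function(e, transport) {
  resp <- issue(e, transport, bcp_request("capabilities"))
  surface_error_diagnostics(resp)
  resp$capabilities %||% capabilities_report(list())
}

surface_error_diagnostics <- function(resp) {
  for (d in resp$diagnostics)
    if (d$level == "error")
      stop("provider error [", d$code, "]: ", d$text, call. = FALSE)
  invisible(resp)
}

#' Count records matching a filter
#'
#' Issues a count-only search (no record payload is transferred). The
#' endpoint's fragment filter, if any, is ANDed in.
#'
#' @inheritParams fetch_capabilities
#' @param filter optional `bcp_filter`
#' @return non-negative integer
#' @export
count_records <- function(e, transport, filter = NULL) {
  resp <- issue(e, transport,
                bcp_request("search", filter = combine_filters(e, filter),
                            count_only = TRUE))
  resp$record_count
}

#' Scan the distinct values of a concept
#'
#' @inheritParams count_records
#' @param concept concept path (must be mapped on the source)
#' @return sorted (code-point order), duplicate-free character vector of
#'   every delivered value of the concept across matching records
#' @export
scan_concept <- function(e, transport, concept, filter = NULL) {
  resp <- issue(e, transport,
                bcp_request("scan", concept = concept,
                            filter = combine_filters(e, filter)))
  surface_error_diagnostics(resp)
  resp$values %||% character(0)
}

#' Retrieve all matching records page by page
#'
#' Issues successive search requests with a paging window until every
#' matching record has been delivered. Lossless and duplication-free for
#' any page size.
#'
#' @inheritParams count_records
#' @param page_size records per request (>= 1)
#' @return list of [unit_record()]s
#' @export
fetch_all_records <- function(e, transport, filter = NULL, page_size = 100) {
  pages <- fetch_pages(e, transport, filter, page_size)
  do.call(c, c(list(), lapply(pages, `[[`, "records")))
}

# shared paging loop; returns the raw page responses
fetch_pages <- function(e, transport, filter = NULL, page_size = 100) {
  stopifnot(page_size >= 1)
  f <- combine_filters(e, filter)
  pages <- list()
  start <- 0L
  repeat {
    resp <- tryCatch(
      issue(e, transport, bcp_request("search", filter = f,
                                      start = start, limit = page_size)),
      bcp_unreachable_error = function(cond) stop(structure(
        class = c("bcp_partial_error", "bcp_unreachable_error", "error",
                  "condition"),
        list(message = sprintf(
               "partial result: page fetch failed at offset %d for %s",
               start, e$url),
             call = NULL, url = e$url, offset = start))))
    pages <- c(pages, list(resp))
    n_served <- length(resp$records)
    start <- start + n_served
    if (start >= resp$record_count || n_served == 0L) break
  }
  pages
}

#' Derive the full counting statistics for a concept
#'
#' `total` is the number of delivered value occurrences of the concept
#' across matching records (retrieved page by page), `distinct` the length
#' of the scan result, and `dropped` the sum of drop-report diagnostic
#' counts accumulated during retrieval.
#'
#' @inheritParams scan_concept
#' @param page_size records per search page
#' @return a [concept_stats_row()]
#' @export
concept_stats <- function(e, transport, concept, filter = NULL,
                          page_size = 100) {
  pages <- fetch_pages(e, transport, filter, page_size)
  total <- 0L
  dropped <- 0L
  for (resp in pages) {
    for (r in resp$records) total <- total + occ_count(r, concept)
    for (d in resp$diagnostics)
      if (d$code == DROP_DIAG_CODE && identical(d$concept, concept))
        dropped <- dropped + d$count
  }
  distinct <- length(scan_concept(e, transport, concept, filter))
  concept_stats_row(concept, total = total, distinct = distinct,
                    dropped = dropped)
}

#' Date of last modification reported by a source
#'
#' Read from the response envelope's `lastModified` stamp of a count-only
#' search.
#'
#' @inheritParams fetch_capabilities
#' @return ISO-8601 date string or `NULL`
#' @export
last_modified_date <- function(e, transport) {
  resp <- issue(e, transport, bcp_request("search", count_only = TRUE,
                                          filter = e$default_filter))
  resp$last_modified
}
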