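#' @title Wire-level request/response dialect
#' @description
#' The toolkit speaks an XML-over-HTTP dialect with three request kinds:
#' `capabilities` (which concepts a source maps, with searchability and
#' declared data type), `search` (unit records or a record count, filterable
#' and pageable) and `scan` (the distinct values of one concept). Every
#' request declares protocol version "1.3". Responses carry diagnostics
#' (info/warning/error messages); drop-report diagnostics carry a concept
#' path and an occurrence count.
#'
#' Request document structure:
#' ```
#' <request version="1.3" kind="search" countOnly="false" start="0" limit="10">
#'   <filter>...one filter fragment...</filter>
#' </request>
#' <request version="1.3" kind="scan">
#'   <concept>/DataSets/DataSet/Units/Unit/UnitID</concept>
#' </request>
#' ```
#' Response documents mirror the request kind and contain `<diagnostics>`,
#' and one of `<records>` + `<recordCount>` + `<datasetMeta>` blocks
#' (search), `<values>` (scan) or `<capabilities>` (capabilities).
#' @name protocol
NULL

PROTOCOL_VERSION <- "1.3"
REQUEST_KINDS <- c("capabilities", "search", "scan")
DROP_REASONS <- c("missing_mandatory", "parent_missing", "invalid_encoding",
                  "outside_value_list")
DROP_DIAG_CODE <- "droppedValue"

#' Construct a unit record
#'
#' A unit record is one collection object: a non-empty unit identifier plus
#' a mapping from concept paths to ordered, possibly multi-valued character
#' vectors. Every listed path carries at least one value; an absent path
#' means the concept is null for this record.
#'
#' @param unit_id non-empty string
#' @param values named list, concept path -> character vector (length >= 1)
#' @return object of class `unit_record`
#' @export
unit_record <- function(unit_id, values = list()) {
  if (!is.character(unit_id) || length(unit_id) != 1L || !nzchar(unit_id))
    stop("unit_id must be a non-empty string", call. = FALSE)
  if (length(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      stop("values must be a named list keyed by concept path", call. = FALSE)
    for (p in names(values)) {
      concept_path(p)
      if (!is.character(values[[p]]) || length(values[[p]]) < 1L)
        stop("values at ", p, " must be a character vector of length >= 1",
             call. = FALSE)
    }
  }
  structure(list(unit_id = unit_id, values = values), class = "unit_record")
}

#' Construct a request envelope
#'
#' @param kind one of `capabilities`, `search`, `scan`
#' @param concept concept path (required for `scan`)
#' @param filter optional `bcp_filter` (search/scan only)
#' @param count_only logical; search returns only the record count
#' @param start,limit paging window for search (`start` >= 0, `limit` >= 1)
#' @return object of class `bcp_request`
#' @export
bcp_request <- function(kind, concept = NULL, filter = NULL,
                        count_only = FALSE, start = NULL, limit = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% REQUEST_KINDS)
    stop("request kind must be one of: ", paste(REQUEST_KINDS, collapse = ", "),
         call. = FALSE)
  if (kind == "scan" && is.null(concept))
    stop("scan request requires a concept", call. = FALSE)
  if (!is.null(concept)) concept <- concept_path(concept)
  if (kind == "capabilities" && (!is.null(filter) || !is.null(start) || !is.null(limit)))
    stop("capabilities request carries neither filter nor paging", call. = FALSE)
  if (!is.null(filter) && !inherits(filter, "bcp_filter"))
    stop("filter must be a bcp_filter", call. = FALSE)
  if (!is.null(start) && (start < 0 || start != trunc(start)))
    stop("paging start must be a non-negative integer", call. = FALSE)
  if (!is.null(limit) && (limit < 1 || limit != trunc(limit)))
    stop("paging limit must be a positive integer", call. = FALSE)
  structure(list(kind = kind, concept = concept, filter = filter,
                 count_only = isTRUE(count_only),
                 start = if (!is.null(start)) as.integer(start),
                 limit = if (!is.null(limit)) as.integer(limit),
                 protocol_version = PROTOCOL_VERSION),
            class = "bcp_request")
}

#' Serialize a request envelope to XML text
#'
#' Deterministic: equal envelopes produce byte-identical documents.
#'
#' @param envelope a `bcp_request`
#' @return XML document text (UTF-8)
#' @export
build_request <- function(envelope) {
  if (!inherits(envelope, "bcp_request"))
    stop("envelope must be a bcp_request", call. = FALSE)
  e <- envelope
  attrs <- sprintf(' version="%s" kind="%s"', e$protocol_version, e$kind)
  if (e$kind == "search") {
    attrs <- paste0(attrs, sprintf(' countOnly="%s"',
                                   if (e$count_only) "true" else "false"))
    if (!is.null(e$start)) attrs <- paste0(attrs, sprintf(' start="%d"', e$start))
    if (!is.null(e$limit)) attrs <- paste0(attrs, sprintf(' limit="%d"', e$limit))
  }
  body <- ""
  if (!is.null(e$concept))
    body <- paste0(body, sprintf("<concept>%s</concept>", xml_esc_text(e$concept)))
  if (!is.null(e$filter))
    body <- paste0(body, "<filter>", serialize_filter(e$filter), "</filter>")
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         "<request", attrs, ">", body, "</request>")
}

#' Parse a request document
#'
#' Inverse of [build_request()]: `parse_request(build_request(e))` is
#' structurally equal to `e` for every valid envelope.
#'
#' @param text XML document text
#' @return a `bcp_request`
#' @export
parse_request <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("malformed request XML: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "request")
    stop("not a request document (root element '", xml2::xml_name(root), "')",
         call. = FALSE)
  version <- xml2::xml_attr(root, "version")
  if (is.na(version))
    stop("request is missing the required version attribute", call. = FALSE)
  if (version != PROTOCOL_VERSION)
    stop("unsupported protocol version '", version, "' (expected ",
         PROTOCOL_VERSION, ")", call. = FALSE)
  kind <- xml2::xml_attr(root, "kind")
  if (is.na(kind) || !kind %in% REQUEST_KINDS)
    stop("unknown request kind '", kind, "'", call. = FALSE)
  cnode <- xml2::xml_find_first(root, "./concept")
  concept <- if (inherits(cnode, "xml_node")) xml2::xml_text(cnode) else NULL
  fnode <- xml2::xml_find_first(root, "./filter")
  filter <- if (inherits(fnode, "xml_node"))
    parse_filter_node(xml2::xml_child(fnode)) else NULL
  start <- xml2::xml_attr(root, "start")
  limit <- xml2::xml_attr(root, "limit")
  bcp_request(kind, concept = concept, filter = filter,
              count_only = identical(xml2::xml_attr(root, "countOnly"), "true"),
              start = if (!is.na(start)) as.integer(start),
              limit = if (!is.na(limit)) as.integer(limit))
}

#' Construct a diagnostic message
#'
#' @param level `info`, `warning` or `error`
#' @param code short machine tag; drop reports use code `droppedValue`
#' @param text free-text message
#' @param concept,count required for drop-report diagnostics
#' @return object of class `bcp_diagnostic`
#' @export
bcp_diagnostic <- function(level, code, text, concept = NULL, count = NULL) {
  level <- match.arg(level, c("info", "warning", "error"))
  if (code == DROP_DIAG_CODE && (is.null(concept) || is.null(count)))
    stop("drop-report diagnostics carry both concept and count", call. = FALSE)
  structure(list(level = level, code = code, text = text,
                 concept = concept,
                 count = if (!is.null(count)) as.integer(count)),
            class = "bcp_diagnostic")
}

new_response <- function(kind, record_count = NULL, records = NULL,
                         values = NULL, capabilities = NULL,
                         diagnostics = list(), last_modified = NULL,
                         dataset_meta = NULL, n_dataset_blocks = 0L) {
  structure(list(kind = kind, record_count = record_count, records = records,
                 values = values, capabilities = capabilities,
                 diagnostics = diagnostics, last_modified = last_modified,
                 dataset_meta = dataset_meta,
                 n_dataset_blocks = as.integer(n_dataset_blocks)),
            class = "bcp_response")
}

serialize_diag <- function(d) {
  attrs <- sprintf(' level="%s" code="%s"', d$level, xml_esc_attr(d$code))
  if (!is.null(d$concept))
    attrs <- paste0(attrs, sprintf(' concept="%s"', xml_esc_attr(d$concept)))
  if (!is.null(d$count))
    attrs <- paste0(attrs, sprintf(' count="%d"', d$count))
  sprintf("<diagnostic%s>%s</diagnostic>", attrs, xml_esc_text(d$text))
}

serialize_record <- function(r) {
  vals <- character(0)
  for (p in names(r$values))
    vals <- c(vals, sprintf('<value path="%s">%s</value>', xml_esc_attr(p),
                            xml_esc_text(r$values[[p]])))
  sprintf('<unit id="%s">%s</unit>', xml_esc_attr(r$unit_id),
          paste(vals, collapse = ""))
}

#' Serialize a response envelope to XML text
#'
#' @param resp a `bcp_response`
#' @return XML document text
#' @export
build_response <- function(resp) {
  stopifnot(inherits(resp, "bcp_response"))
  attrs <- sprintf(' version="%s" kind="%s"', PROTOCOL_VERSION, resp$kind)
  if (!is.null(resp$last_modified))
    attrs <- paste0(attrs, sprintf(' lastModified="%s"',
                                   xml_esc_attr(resp$last_modified)))
  body <- sprintf("<diagnostics>%s</diagnostics>",
                  paste(vapply(resp$diagnostics, serialize_diag, character(1)),
                        collapse = ""))
  if (!is.null(resp$record_count))
    body <- paste0(body, sprintf("<recordCount>%d</recordCount>",
                                 as.integer(resp$record_count)))
  if (!is.null(resp$dataset_meta) && resp$n_dataset_blocks > 0L) {
    meta_vals <- character(0)
    for (p in names(resp$dataset_meta))
      meta_vals <- c(meta_vals, sprintf('<value path="%s">%s</value>',
                                        xml_esc_attr(p),
                                        xml_esc_text(resp$dataset_meta[[p]])))
    block <- sprintf("<datasetMeta>%s</datasetMeta>",
                     paste(meta_vals, collapse = ""))
    body <- paste0(body, paste(rep(block, resp$n_dataset_blocks), collapse = ""))
  }
  if (!is.null(resp$records))
    body <- paste0(body, sprintf("<records>%s</records>",
                                 paste(vapply(resp$records, serialize_record,
                                              character(1)), collapse = "")))
  if (!is.null(resp$values))
    body <- paste0(body, sprintf("<values>%s</values>",
                                 paste(sprintf("<value>%s</value>",
                                               xml_esc_text(resp$values)),
                                       collapse = "")))
  if (!is.null(resp$capabilities)) {
    caps <- vapply(resp$capabilities$concepts, function(cc)
      sprintf('<concept path="%s" searchable="%s" datatype="%s"/>',
              xml_esc_attr(cc$path), if (cc$searchable) "true" else "false",
              xml_esc_attr(cc$datatype)), character(1))
    body <- paste0(body, sprintf("<capabilities>%s</capabilities>",
                                 paste(caps, collapse = "")))
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         "<response", attrs, ">", body, "</response>")
}

#' Parse a response document
#'
#' @param text XML document text
#' @return a `bcp_response`
#' @export
parse_response <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("malformed response XML: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "response")
    stop("not a response document", call. = FALSE)
  kind <- xml2::xml_attr(root, "kind")
  lm <- xml2::xml_attr(root, "lastModified")
  diags <- lapply(xml2::xml_find_all(root, "./diagnostics/diagnostic"),
                  function(d) {
    concept <- xml2::xml_attr(d, "concept")
    count <- xml2::xml_attr(d, "count")
    bcp_diagnostic(xml2::xml_attr(d, "level"), xml2::xml_attr(d, "code"),
                   xml2::xml_text(d),
                   concept = if (!is.na(concept)) concept,
                   count = if (!is.na(count)) as.integer(count))
  })
  rc_node <- xml2::xml_find_first(root, "./recordCount")
  record_count <- if (inherits(rc_node, "xml_node"))
    as.integer(xml2::xml_text(rc_node)) else NULL
  recs_parent <- xml2::xml_find_first(root, "./records")
  records <- NULL
  if (inherits(recs_parent, "xml_node")) {
    records <- lapply(xml2::xml_find_all(recs_parent, "./unit"), function(u) {
      vnodes <- xml2::xml_find_all(u, "./value")
      paths <- xml2::xml_attr(vnodes, "path")
      txts <- xml2::xml_text(vnodes)
      vals <- split(txts, factor(paths, levels = unique(paths)))
      unit_record(xml2::xml_attr(u, "id"), as.list(vals))
    })
  }
  vparent <- xml2::xml_find_first(root, "./values")
  values <- if (inherits(vparent, "xml_node"))
    xml2::xml_text(xml2::xml_find_all(vparent, "./value")) else NULL
  cparent <- xml2::xml_find_first(root, "./capabilities")
  capabilities <- NULL
  if (inherits(cparent, "xml_node")) {
    concepts <- lapply(xml2::xml_find_all(cparent, "./concept"), function(cc)
      list(path = xml2::xml_attr(cc, "path"),
           searchable = identical(xml2::xml_attr(cc, "searchable"), "true"),
           datatype = xml2::xml_attr(cc, "datatype")))
    capabilities <- capabilities_report(concepts)
  }
  meta_blocks <- xml2::xml_find_all(root, "./datasetMeta")
  dataset_meta <- NULL
  if (length(meta_blocks)) {
    vnodes <- xml2::xml_find_all(meta_blocks[[1]], "./value")
    dataset_meta <- as.list(stats::setNames(xml2::xml_text(vnodes),
                                            xml2::xml_attr(vnodes, "path")))
  }
  new_response(kind, record_count = record_count, records = records,
               values = values, capabilities = capabilities,
               diagnostics = diags,
               last_modified = if (!is.na(lm)) lm,
               dataset_meta = dataset_meta,
               n_dataset_blocks = length(meta_blocks))
}

#' Capabilities report
#'
#' A source's self-description: every mapped concept with its searchable
#' flag (values come from an atomized, filterable database field rather
#' than literal mapping text) and its declared data type.
#'
#' @param concepts list of `list(path=, searchable=, datatype=)`
#' @return object of class `capabilities_report`
#' @export
capabilities_report <- function(concepts) {
  paths <- vapply(concepts, `[[`, character(1), "path")
  if (anyDuplicated(paths))
    stop("capabilities concept paths must be unique", call. = FALSE)
  structure(list(concepts = concepts), class = "capabilities_report")
}

#' @export
print.capabilities_report <- function(x, ...) {
  cat("<capabilities>", length(x$concepts), "mapped concepts\n")
  for (cc in x$concepts)
    cat(sprintf("  %s [%s%s]\n", cc$path, cc$datatype,
                if (cc$searchable) ", searchable" else ""))
  invisible(x)
}

capability_paths <- function(caps) {
  vapply(caps$concepts, `[[`, character(1), "path")
}
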