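#' @title Mapping checker
#' @description
#' Audits the schema mapping of a single data source: inventories every
#' mapped concept with its x-path, searchability and declared data type;
#' shows sample values of the first records so a domain expert can judge
#' content plausibility; counts total, distinct and dropped values per
#' concept; and validates the mapping against a switchable target-schema
#' requirement profile (mandatory / unique constraints), flagging issues
#' such as missing mandatory elements, duplicated values of a
#' unique-constrained concept, or dataset metadata repeated once per unit
#' — the normalization defect that prevents correct indexing by a
#' harvester. Reports render as HTML (default) or XML for further
#' machine processing.
#' @name mapchecker
NULL

ISSUE_CODES <- c("missing_mandatory", "duplicate_unique", "dataset_repetition",
                 "unmapped_target", "not_searchable")

#' Construct an issue
#'
#' @param severity `warning` or `error`
#' @param code one of `missing_mandatory`, `duplicate_unique`,
#'   `dataset_repetition`, `unmapped_target`, `not_searchable`
#' @param message human-readable description
#' @param target_concept,path whichever the code requires
#' @return object of class `mapping_issue`
#' @export
mapping_issue <- function(severity, code, message, target_concept = NULL,
                          path = NULL) {
  severity <- match.arg(severity, c("warning", "error"))
  code <- match.arg(code, ISSUE_CODES)
  if (code %in% c("missing_mandatory", "unmapped_target") &&
      is.null(target_concept))
    stop(code, " issues require a target_concept", call. = FALSE)
  if (code %in% c("duplicate_unique", "not_searchable") && is.null(path))
    stop(code, " issues require a concept path", call. = FALSE)
  structure(list(severity = severity, code = code, message = message,
                 target_concept = target_concept, path = path),
            class = "mapping_issue")
}

#' Check a mapping against a target-schema profile
#'
#' Verifies, rule by rule (profile order), whether the source's mapped
#' elements meet the target schema's requirements, i.e. whether the
#' content is ready for transformation to the target format:
#' * a mandatory target concept with no mapped alternative source path
#'   gives an error `missing_mandatory`;
#' * a unique-constrained concept whose mapped path delivers fewer
#'   distinct than total values gives an error `duplicate_unique`;
#' * a mapped source path that is not searchable gives a warning
#'   `not_searchable` (it cannot be filtered, which hampers harvesting
#'   and debugging);
#' * a non-mandatory target concept with no mapped path gives a warning
#'   `unmapped_target`.
#'
#' @param caps a [capabilities_report()]
#' @param stats named list, concept path -> [concept_stats_row()]
#' @param profile a [load_profile()] result
#' @return list of [mapping_issue()]s in profile rule order
#' @export
check_compliance <- function(caps, stats, profile) {
  stopifnot(inherits(caps, "capabilities_report"),
            inherits(profile, "target_profile"))
  mapped <- capability_paths(caps)
  issues <- list()
  add <- function(i) issues[[length(issues) + 1L]] <<- i
  for (rule in profile$rules) {
    alt <- intersect(rule$source_paths, mapped)
    if (!length(alt)) {
      if (rule$mandatory)
        add(mapping_issue("error", "missing_mandatory",
          sprintf("mandatory target concept '%s' has no mapped source path (tried: %s)",
                  rule$target_concept, paste(rule$source_paths, collapse = ", ")),
          target_concept = rule$target_concept))
      else
        add(mapping_issue("warning", "unmapped_target",
          sprintf("target concept '%s' is not mapped", rule$target_concept),
          target_concept = rule$target_concept))
      next
    }
    path <- alt[[1]]
    st <- stats[[path]]
    if (rule$unique && !is.null(st) && st$distinct < st$total)
      add(mapping_issue("error", "duplicate_unique",
        sprintf("concept %s must be unique for target '%s' but delivers %d total vs %d distinct values",
                path, rule$target_concept, st$total, st$distinct),
        target_concept = rule$target_concept, path = path))
    cc <- Filter(function(x) x$path == path, caps$concepts)[[1]]
    if (!cc$searchable)
      add(mapping_issue("warning", "not_searchable",
        sprintf("concept %s (target '%s') is mapped from literal text and cannot be filtered",
                path, rule$target_concept),
        target_concept = rule$target_concept, path = path))
  }
  issues
}

#' Detect dataset metadata repeated per unit
#'
#' When collection metadata and units are joined without normalization,
#' the dataset block is repeated as many times as there are units, which
#' prevents correct indexing by harvesting services. Flags a warning iff
#' the response repeats the dataset block once per unit and more than one
#' unit was served; a single-unit response is ambiguous and not flagged.
#'
#' @param resp a search `bcp_response`
#' @return a [mapping_issue()] or `NULL`
#' @export
check_dataset_repetition <- function(resp) {
  stopifnot(inherits(resp, "bcp_response"), resp$kind == "search")
  n_units <- length(resp$records)
  if (n_units > 1L && resp$n_dataset_blocks == n_units)
    return(mapping_issue("warning", "dataset_repetition",
      sprintf("dataset metadata repeated %d times for %d units: source lacks dataset/unit normalization",
              resp$n_dataset_blocks, n_units),
      path = "Dataset"))
  NULL
}

#' Audit one data source
#'
#' Retrieves the source's capabilities and records, derives per-concept
#' statistics and sample values from the first records, resolves each
#' mapped path to its target concept under the given profile, and runs
#' the compliance and dataset-repetition checks.
#'
#' @param e a [endpoint()]
#' @param transport transport function
#' @param profile a `target_profile`
#' @param sample_size maximum sample values shown per concept (default 5,
#'   drawn from the first records of the response)
#' @param page_size search page size used during retrieval
#' @return object of class `mapping_report`
#' @export
build_mapping_report <- function(e, transport, profile, sample_size = 5,
                                 page_size = 100) {
  stopifnot(sample_size >= 1, inherits(profile, "target_profile"))
  caps <- fetch_capabilities(e, transport)
  pages <- fetch_pages(e, transport, page_size = page_size)
  records <- do.call(c, c(list(), lapply(pages, `[[`, "records")))
  paths <- capability_paths(caps)
  # one retrieval feeds totals, dropped counts and samples for all rows
  total <- stats::setNames(integer(length(paths)), paths)
  dropped <- stats::setNames(integer(length(paths)), paths)
  for (resp in pages)
    for (d in resp$diagnostics)
      if (d$code == DROP_DIAG_CODE && d$concept %in% paths)
        dropped[[d$concept]] <- dropped[[d$concept]] + d$count
  for (r in records)
    for (p in names(r$values))
      if (p %in% paths) total[[p]] <- total[[p]] + length(r$values[[p]])
  stats <- list()
  rows <- list()
  for (cc in caps$concepts) {
    p <- cc$path
    distinct <- length(scan_concept(e, transport, p))
    stats[[p]] <- concept_stats_row(p, total = total[[p]], distinct = distinct,
                                    dropped = dropped[[p]])
    samples <- character(0)
    for (r in records) {
      v <- r$values[[p]]
      if (!is.null(v)) samples <- c(samples, v)
      if (length(samples) >= sample_size) break
    }
    rule <- NULL
    for (rr in profile$rules) if (p %in% rr$source_paths) { rule <- rr; break }
    rows[[length(rows) + 1L]] <- structure(list(
      path = p, searchable = cc$searchable, datatype = cc$datatype,
      target_concept = rule$target_concept,
      samples = utils::head(samples, sample_size),
      stats = stats[[p]],
      constraint_notes = if (!is.null(rule)) {
        notes <- character(0)
        if (rule$mandatory) notes <- c(notes, "mandatory in target schema")
        if (rule$unique) notes <- c(notes, "must be unique in target schema")
        notes
      } else character(0)), class = "mapping_report_row")
  }
  issues <- check_compliance(caps, stats, profile)
  rep_issue <- if (length(pages)) check_dataset_repetition(pages[[1]])
  if (!is.null(rep_issue)) issues <- c(issues, list(rep_issue))
  structure(list(endpoint = e, profile_name = profile$name, rows = rows,
                 issues = issues, generated_at = Sys.time()),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping report> %s (profile '%s'): %d concept(s), %d issue(s)\n",
              x$endpoint$url, x$profile_name, length(x$rows),
              length(x$issues)))
  for (i in x$issues)
    cat(sprintf("  [%s] %s: %s\n", i$severity, i$code, i$message))
  invisible(x)
}

#' Render a mapping report
#'
#' HTML is the default output; XML is supported for further processing by
#' other software. The XML layout is:
#' ```
#' <mappingReport endpoint="..." profile="...">
#'   <row path="..." searchable="true" datatype="string" target="...">
#'     <sample>...</sample>...
#'     <stats total="10" distinct="9" dropped="0"/>
#'     <note>...</note>...
#'   </row>...
#'   <issues>
#'     <issue severity="error" code="missing_mandatory" target="...">msg</issue>
#'   </issues>
#' </mappingReport>
#' ```
#'
#' @param r a `mapping_report`
#' @param format `"html"` (default) or `"xml"`
#' @return document text
#' @export
render_mapping_report <- function(r, format = c("html", "xml")) {
  format <- match.arg(format)
  if (format == "xml") render_report_xml(r) else render_report_html(r)
}

render_report_xml <- function(r) {
  rows <- vapply(r$rows, function(row) {
    attrs <- sprintf(' path="%s" searchable="%s" datatype="%s"',
                     xml_esc_attr(row$path),
                     if (row$searchable) "true" else "false",
                     xml_esc_attr(row$datatype))
    if (!is.null(row$target_concept))
      attrs <- paste0(attrs, sprintf(' target="%s"',
                                     xml_esc_attr(row$target_concept)))
    body <- paste0(
      paste(sprintf("<sample>%s</sample>", xml_esc_text(row$samples)),
            collapse = ""),
      sprintf('<stats total="%d" distinct="%d" dropped="%d"/>',
              row$stats$total, row$stats$distinct, row$stats$dropped),
      paste(sprintf("<note>%s</note>", xml_esc_text(row$constraint_notes)),
            collapse = ""))
    sprintf("<row%s>%s</row>", attrs, body)
  }, character(1))
  issues <- vapply(r$issues, function(i) {
    attrs <- sprintf(' severity="%s" code="%s"', i$severity, i$code)
    if (!is.null(i$target_concept))
      attrs <- paste0(attrs, sprintf(' target="%s"',
                                     xml_esc_attr(i$target_concept)))
    if (!is.null(i$path))
      attrs <- paste0(attrs, sprintf(' concept="%s"', xml_esc_attr(i$path)))
    sprintf("<issue%s>%s</issue>", attrs, xml_esc_text(i$message))
  }, character(1))
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<mappingReport endpoint="%s" profile="%s">',
                 xml_esc_attr(r$endpoint$url), xml_esc_attr(r$profile_name)),
         paste(rows, collapse = ""),
         "<issues>", paste(issues, collapse = ""), "</issues>",
         "</mappingReport>")
}

render_report_html <- function(r) {
  esc <- xml_esc_text
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            sprintf("<title>Mapping report: %s</title></head><body>",
                    esc(r$endpoint$url)),
            sprintf("<h1>Mapping report</h1><p>Source: %s<br/>Profile: %s</p>",
                    esc(r$endpoint$url), esc(r$profile_name)),
            "<table><thead><tr><th>x-path</th><th>searchable</th>",
            "<th>data type</th><th>target concept</th><th>sample values</th>",
            "<th>total</th><th>distinct</th><th>dropped</th>",
            "<th>constraints</th></tr></thead><tbody>")
  for (row in r$rows) {
    html <- c(html, paste0("<tr>",
      sprintf("<td>%s</td>", esc(row$path)),
      sprintf("<td>%s</td>", if (row$searchable) "yes" else "no"),
      sprintf("<td>%s</td>", esc(row$datatype)),
      sprintf("<td>%s</td>", esc(row$target_concept %||% "")),
      sprintf("<td>%s</td>", paste(esc(row$samples), collapse = "; ")),
      sprintf("<td>%d</td><td>%d</td><td>%d</td>", row$stats$total,
              row$stats$distinct, row$stats$dropped),
      sprintf("<td>%s</td>", paste(esc(row$constraint_notes), collapse = "; ")),
      "</tr>"))
  }
  html <- c(html, "</tbody></table>")
  if (length(r$issues)) {
    html <- c(html, '<section class="message-box"><h2>Issues</h2><ul>')
    for (i in r$issues)
      html <- c(html, sprintf('<li class="%s">[%s] %s</li>', i$severity,
                              i$code, esc(i$message)))
    html <- c(html, "</ul></section>")
  }
  paste0(paste(c(html, "</body></html>"), collapse = "\n"), "\n")
}

#' Parse a mapping-report XML document
#'
#' @param text XML text from `render_mapping_report(r, "xml")`
#' @return list with `endpoint_url`, `profile`, `rows`, `issues`
#' @export
parse_mapping_report_xml <- function(text) {
  root <- xml2::xml_root(xml2::read_xml(text))
  rows <- lapply(xml2::xml_find_all(root, "./row"), function(n) {
    st <- xml2::xml_find_first(n, "./stats")
    list(path = xml2::xml_attr(n, "path"),
         searchable = identical(xml2::xml_attr(n, "searchable"), "true"),
         datatype = xml2::xml_attr(n, "datatype"),
         target_concept = {
           t <- xml2::xml_attr(n, "target"); if (!is.na(t)) t
         },
         samples = xml2::xml_text(xml2::xml_find_all(n, "./sample")),
         stats = concept_stats_row(xml2::xml_attr(n, "path"),
                                   as.integer(xml2::xml_attr(st, "total")),
                                   as.integer(xml2::xml_attr(st, "distinct")),
                                   as.integer(xml2::xml_attr(st, "dropped"))),
         constraint_notes = xml2::xml_text(xml2::xml_find_all(n, "./note")))
  })
  issues <- lapply(xml2::xml_find_all(root, "./issues/issue"), function(n) {
    t <- xml2::xml_attr(n, "target"); p <- xml2::xml_attr(n, "concept")
    mapping_issue(xml2::xml_attr(n, "severity"), xml2::xml_attr(n, "code"),
                  xml2::xml_text(n),
                  target_concept = if (!is.na(t)) t,
                  path = if (!is.na(p)) p)
  })
  list(endpoint_url = xml2::xml_attr(root, "endpoint"),
       profile = xml2::xml_attr(root, "profile"),
       rows = rows, issues = issues)
}

#' Scan view of one concept
#'
#' XML document listing every unique delivered value of a concept, the
#' drill-down behind the x-path link of a report row (e.g. all taxon
#' names, localities or multimedia URIs of a source).
#'
#' @inheritParams build_mapping_report
#' @param concept concept path
#' @return XML document text
#' @export
scan_view <- function(e, transport, concept) {
  vals <- tryCatch(scan_concept(e, transport, concept),
                   error = function(cond) cond)
  if (inherits(vals, "condition")) {
    return(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                  sprintf('<scanView concept="%s">', xml_esc_attr(concept)),
                  sprintf('<diagnostic level="error" code="unmappedConcept">%s</diagnostic>',
                          xml_esc_text(conditionMessage(vals))),
                  "</scanView>"))
  }
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf('<scanView concept="%s">', xml_esc_attr(concept)),
         paste(sprintf("<value>%s</value>", xml_esc_text(vals)), collapse = ""),
         "</scanView>")
}
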