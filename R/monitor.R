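#' @title Multi-source monitoring overview
#' @description
#' Builds the network progress overview: one row per registered data
#' source with its record count, date of last modification, optional
#' baseline delta (current minus former-period count), and total/distinct
#' columns for any configured concepts — e.g. taxon names, locality names
#' or multimedia FileURIs, where total and distinct differ as soon as one
#' media object is linked to several records. Rows are grouped by provider
#' group in configuration order; a source that cannot be reached yields a
#' row with status `unreachable` and never aborts the build. Fresh cache
#' entries are used instead of live requests.
#' @name monitor
NULL

STATUS_CACHE_INTERVAL_DAYS <- 1 / 24  # unreachable status is retried hourly

#' Build the monitor overview
#'
#' @param cfg a [load_config()] result
#' @param transport transport function (see [mock_transport()])
#' @param cache optional [file_cache()]; `NULL` disables caching
#' @param now current instant (`POSIXct`)
#' @param renew character vector of source names whose cache entries are
#'   force-invalidated before the build (the manual renew action)
#' @return object of class `bms_overview`
#' @export
build_overview <- function(cfg, transport, cache = NULL, now = Sys.time(),
                           renew = character(0)) {
  stopifnot(inherits(cfg, "monitor_config"))
  rows <- lapply(cfg$sources, function(src)
    build_row(src, transport, cache, now, cfg$cache_interval_days,
              force_renew = src$name %in% renew))
  names(rows) <- vapply(cfg$sources, `[[`, character(1), "name")
  grouped <- lapply(cfg$groups, function(g)
    rows[vapply(cfg$sources, function(s) s$group == g, logical(1))])
  names(grouped) <- cfg$groups
  structure(list(groups = grouped, generated_at = now,
                 cache_interval_days = cfg$cache_interval_days),
            class = "bms_overview")
}

source_keys <- function(src) {
  url <- src$endpoint$url
  f <- src$filter
  list(count = cache_key(url, "count", filter = f),
       last_modified = cache_key(url, "last_modified", filter = f),
       status = cache_key(url, "status", filter = f),
       stats = stats::setNames(lapply(src$concept_columns, function(cp)
         cache_key(url, "stats", concept = cp, filter = f)),
         src$concept_columns))
}

build_row <- function(src, transport, cache, now, interval_days, force_renew) {
  keys <- source_keys(src)
  if (force_renew && !is.null(cache)) {
    cache_renew(cache, keys$count)
    cache_renew(cache, keys$last_modified)
    cache_renew(cache, keys$status)
    for (k in keys$stats) cache_renew(cache, k)
  }
  # a recent unreachable verdict short-circuits the fetch (1 h TTL), so a
  # down provider does not stall every rebuild, but never poisons the
  # long-lived result cache
  if (!is.null(cache)) {
    st <- cache_get(cache, keys$status, now, STATUS_CACHE_INTERVAL_DAYS)
    if (identical(st, "unreachable")) return(unreachable_row(src))
  }
  out <- tryCatch({
    record_count <- with_cache(cache, keys$count, now, interval_days,
      function() count_records(src$endpoint, transport))
    last_mod <- with_cache(cache, keys$last_modified, now, interval_days,
      function() list(value = last_modified_date(src$endpoint, transport)))
    stats <- lapply(src$concept_columns, function(cp)
      as_concept_stats(with_cache(cache, keys$stats[[cp]], now, interval_days,
        function() unclass(concept_stats(src$endpoint, transport, cp)))))
    names(stats) <- src$concept_columns
    list(record_count = as.integer(record_count),
         last_modified = last_mod$value, stats = stats)
  }, bcp_unreachable_error = function(cond) cond)
  if (inherits(out, "condition")) {
    if (!is.null(cache))
      cache_put(cache, keys$status, "unreachable", now)
    return(unreachable_row(src))
  }
  delta <- if (!is.null(src$baseline_count))
    out$record_count - src$baseline_count
  monitor_row(src, status = "ok", record_count = out$record_count,
              last_modified = out$last_modified, concept_stats = out$stats,
              delta = delta)
}

as_concept_stats <- function(x) {
  if (inherits(x, "concept_stats")) return(x)
  concept_stats_row(x$concept, x$total, x$distinct, x$dropped)
}

unreachable_row <- function(src) {
  monitor_row(src, status = "unreachable", record_count = NULL,
              last_modified = NULL, concept_stats = NULL, delta = NULL)
}

monitor_row <- function(src, status, record_count, last_modified,
                        concept_stats, delta) {
  status <- match.arg(status, c("ok", "stale_cache", "unreachable"))
  if (status == "unreachable" && !is.null(record_count))
    stop("unreachable rows carry no counts", call. = FALSE)
  structure(list(source = src, record_count = record_count,
                 last_modified = last_modified,
                 concept_stats = concept_stats, delta = delta,
                 status = status),
            class = "monitor_row")
}

#' @export
print.bms_overview <- function(x, ...) {
  cat(sprintf("<overview> generated %s, cache interval %g day(s)\n",
              format(x$generated_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
              x$cache_interval_days))
  for (g in names(x$groups)) {
    cat(sprintf("[%s]\n", g))
    for (row in x$groups[[g]]) {
      if (row$status == "ok")
        cat(sprintf("  %-20s %6d records%s\n", row$source$name,
                    row$record_count,
                    if (!is.null(row$delta))
                      sprintf(" (%+d vs baseline)", row$delta) else ""))
      else
        cat(sprintf("  %-20s [%s]\n", row$source$name, row$status))
    }
  }
  invisible(x)
}

overview_rows <- function(o) {
  out <- list()
  for (g in names(o$groups)) out <- c(out, o$groups[[g]])
  out
}

overview_concept_columns <- function(o) {
  cols <- character(0)
  for (row in overview_rows(o))
    cols <- c(cols, setdiff(row$source$concept_columns, cols))
  cols
}

#' Export the overview as tab-delimited text
#'
#' The format regular project reports are compiled from. One header row,
#' then one line per source: `group`, `name`, `endpoint`, `status`,
#' `records`, `last_modified`, `delta`, `links`, then a
#' `<path>.total` / `<path>.distinct` pair for every configured concept
#' column (union over sources, config order). Missing values are empty
#' cells. UTF-8, trailing newline.
#'
#' @param o a `bms_overview`
#' @return TSV text
#' @export
export_tsv <- function(o) {
  stopifnot(inherits(o, "bms_overview"))
  cols <- overview_concept_columns(o)
  header <- c("group", "name", "endpoint", "status", "records",
              "last_modified", "delta", "links",
              unlist(lapply(cols, function(cp)
                c(paste0(cp, ".total"), paste0(cp, ".distinct")))))
  lines <- vapply(overview_rows(o), function(row) {
    cells <- c(row$source$group, row$source$name, row$source$endpoint$url,
               row$status,
               if (is.null(row$record_count)) "" else as.character(row$record_count),
               row$last_modified %||% "",
               if (is.null(row$delta)) "" else sprintf("%+d", row$delta),
               paste(vapply(row$source$links, function(lk)
                 paste0(lk$label, "=", lk$url), character(1)), collapse = " "))
    for (cp in cols) {
      st <- row$concept_stats[[cp]]
      cells <- c(cells, if (is.null(st)) c("", "")
                 else c(as.character(st$total), as.character(st$distinct)))
    }
    paste(cells, collapse = "\t")
  }, character(1))
  paste0(paste(c(paste(header, collapse = "\t"), lines), collapse = "\n"), "\n")
}

#' Parse an exported TSV back into a data frame
#'
#' Round-trip companion of [export_tsv()], mainly for checking exports.
#'
#' @param text TSV text
#' @return data frame, one row per source
#' @export
parse_overview_tsv <- function(text) {
  utils::read.delim(text = text, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

#' Render the overview as HTML or JSON
#'
#' HTML mirrors the grouped monitor page: one section per provider group
#' with a table of its sources and their useful links as anchors. JSON is
#' a faithful serialization that [parse_overview_json()] restores.
#'
#' @param o a `bms_overview`
#' @param format `"html"` or `"json"`
#' @return document text
#' @export
render_overview <- function(o, format = c("html", "json")) {
  format <- match.arg(format)
  if (format == "json") return(overview_to_json(o))
  cols <- overview_concept_columns(o)
  esc <- xml_esc_text
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            "<title>Data-source monitor</title></head><body>",
            sprintf("<p>Generated %s; cache interval %g day(s)</p>",
                    format(o$generated_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    o$cache_interval_days))
  for (g in names(o$groups)) {
    html <- c(html, sprintf('<section class="group" id="group-%s">', esc(g)),
              sprintf("<h2>%s</h2>", esc(g)), "<table><thead><tr>",
              paste0("<th>", esc(c("name", "endpoint", "status", "records",
                                   "last modified", "delta", "links",
                                   unlist(lapply(cols, function(cp)
                                     c(paste0(cp, " total"),
                                       paste0(cp, " distinct")))))),
                     "</th>", collapse = ""),
              "</tr></thead><tbody>")
    for (row in o$groups[[g]]) {
      links <- paste(vapply(row$source$links, function(lk)
        sprintf('<a href="%s">%s</a>', xml_esc_attr(lk$url), esc(lk$label)),
        character(1)), collapse = " ")
      cells <- c(esc(row$source$name), esc(row$source$endpoint$url),
                 row$status,
                 if (is.null(row$record_count)) "" else row$record_count,
                 esc(row$last_modified %||% ""),
                 if (is.null(row$delta)) "" else sprintf("%+d", row$delta),
                 links)
      for (cp in cols) {
        st <- row$concept_stats[[cp]]
        cells <- c(cells, if (is.null(st)) c("", "") else c(st$total, st$distinct))
      }
      html <- c(html, paste0("<tr>", paste0("<td>", cells, "</td>",
                                            collapse = ""), "</tr>"))
    }
    html <- c(html, "</tbody></table></section>")
  }
  paste0(paste(c(html, "</body></html>"), collapse = "\n"), "\n")
}

overview_to_json <- function(o) {
  groups <- lapply(o$groups, function(rows) lapply(unname(rows), function(row)
    list(group = row$source$group, name = row$source$name,
         endpoint = row$source$endpoint$url,
         filter = if (!is.null(row$source$filter))
           filter_to_text(row$source$filter),
         baseline_count = row$source$baseline_count,
         links = row$source$links,
         concept_columns = as.list(row$source$concept_columns),
         status = row$status, record_count = row$record_count,
         last_modified = row$last_modified, delta = row$delta,
         concept_stats = lapply(row$concept_stats, unclass))))
  jsonlite::toJSON(list(generated_at = format(o$generated_at,
                                              "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                        cache_interval_days = o$cache_interval_days,
                        groups = groups),
                   auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
}

#' Restore an overview from its JSON rendering
#'
#' @param text JSON text produced by `render_overview(o, "json")`
#' @return a `bms_overview`
#' @export
parse_overview_json <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  groups <- lapply(x$groups, function(rows) {
    out <- lapply(rows, function(rj) {
      src <- data_source(rj$name, rj$group, rj$endpoint,
                         filter = if (!is.null(rj$filter))
                           parse_filter_text(rj$filter),
                         baseline_count = rj$baseline_count,
                         links = lapply(rj$links, function(lk)
                           list(label = lk$label, url = lk$url)),
                         concept_columns = unlist(rj$concept_columns) %||%
                           character(0))
      stats <- if (!is.null(rj$concept_stats) && length(rj$concept_stats))
        lapply(rj$concept_stats, as_concept_stats)
      monitor_row(src, status = rj$status,
                  record_count = if (!is.null(rj$record_count))
                    as.integer(rj$record_count),
                  last_modified = rj$last_modified,
                  concept_stats = stats,
                  delta = if (!is.null(rj$delta)) as.integer(rj$delta))
    })
    names(out) <- vapply(out, function(r) r$source$name, character(1))
    out
  })
  structure(list(groups = groups,
                 generated_at = as.POSIXct(x$generated_at,
                                           format = "%Y-%m-%dT%H:%M:%S",
                                           tz = "UTC"),
                 cache_interval_days = x$cache_interval_days),
            class = "bms_overview")
}
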