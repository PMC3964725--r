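#' @title Configuration registry
#' @description
#' The monitor is driven by a plain-text INI configuration and by
#' target-schema requirement profiles in tab-delimited text, so that
#' network coordinators can maintain them without programming.
#'
#' INI grammar (documented contract):
#' ```
#' [general]
#' cache_interval_days = 7
#' default_profile = default
#' profile.default = profiles/default.tsv
#' profile.paleontology = profiles/paleontology.tsv
#'
#' [group:Herbaria]
#' bgbm.url = http://example.org/pywrapper.cgi?dsa=herbar
#' bgbm.filter = isNotNull(/DataSets/DataSet/Units/Unit/UnitID)
#' bgbm.baseline = 1000
#' bgbm.link.portal = http://example.org/portal
#' bgbm.concepts = /path/one;/path/two
#' ```
#' One `[group:<name>]` section per provider group; within it, keys are
#' `<source>.url` (required), `<source>.filter` (compact prefix filter
#' text, see [parse_filter_text()]), `<source>.baseline` (record count of
#' a former funding period, for the automatically calculated delta),
#' `<source>.link.<label>` (useful-links column) and `<source>.concepts`
#' (`;`-separated concept columns). Unknown keys produce warnings, not
#' errors. Lines starting with `#` or `;` are comments.
#' @name registry
NULL

#' Load the monitor configuration
#'
#' @param text INI text (single string or character vector of lines), or
#'   use `file` to read from disk
#' @param file path to an INI file
#' @return object of class `monitor_config`: `groups` (ordered names),
#'   `sources` (list of source descriptors in declared order),
#'   `cache_interval_days` (default 7), `profiles` (named list of file
#'   paths), `default_profile`
#' @export
load_config <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("provide INI text or a file path", call. = FALSE)
    text <- readLines(file, encoding = "UTF-8", warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  groups <- character(0)
  sources <- list()
  general <- list()
  section <- NULL
  # per-group accumulation: named list srcname -> fields
  grp_sources <- list()
  grp_order <- list()
  flush_group <- function(gname) {
    for (nm in grp_order[[gname]]) {
      fields <- grp_sources[[gname]][[nm]]
      if (is.null(fields$url))
        stop("source '", nm, "' in group '", gname, "' has no url",
             call. = FALSE)
      sources[[length(sources) + 1L]] <<- data_source(
        name = nm, group = gname, url = fields$url,
        filter = fields$filter, baseline_count = fields$baseline,
        links = fields$links %||% list(),
        concept_columns = fields$concepts %||% character(0))
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, ";")) next
    if (grepl("^\\[.*\\]$", line)) {
      if (!is.null(section) && startsWith(section, "group:"))
        flush_group(sub("^group:", "", section))
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (startsWith(section, "group:")) {
        gname <- sub("^group:", "", section)
        if (gname %in% groups)
          stop("duplicate group '", gname, "' at line ", i, call. = FALSE)
        groups <- c(groups, gname)
        grp_sources[[gname]] <- list()
        grp_order[[gname]] <- character(0)
      } else if (section != "general") {
        warning("unknown section [", section, "] at line ", i, call. = FALSE)
      }
      next
    }
    kv <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop("cannot parse line ", i, ": ", line, call. = FALSE)
    key <- trimws(kv[2]); value <- trimws(kv[3])
    if (is.null(section))
      stop("key outside any section at line ", i, call. = FALSE)
    if (section == "general") {
      if (key == "cache_interval_days") {
        general$cache_interval_days <- as.numeric(value)
      } else if (key == "default_profile") {
        general$default_profile <- value
      } else if (startsWith(key, "profile.")) {
        general$profiles[[sub("^profile\\.", "", key)]] <- value
      } else {
        warning("unknown [general] key '", key, "' at line ", i, call. = FALSE)
      }
      next
    }
    gname <- sub("^group:", "", section)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      warning("unknown key '", key, "' at line ", i, call. = FALSE)
      next
    }
    src <- parts[1]; field <- parts[2]
    if (!src %in% grp_order[[gname]]) {
      if (field == "url" && src %in% names(grp_sources[[gname]]))
        stop("duplicate source '", src, "' in group '", gname, "' at line ", i,
             call. = FALSE)
      grp_order[[gname]] <- c(grp_order[[gname]], src)
      grp_sources[[gname]][[src]] <- list()
    }
    fields <- grp_sources[[gname]][[src]]
    if (field == "url") {
      if (!is.null(fields$url))
        stop("duplicate source '", src, "' in group '", gname, "' at line ", i,
             call. = FALSE)
      fields$url <- value
    } else if (field == "filter") {
      fields$filter <- tryCatch(parse_filter_text(value),
        error = function(err) stop("unparsable filter at line ", i, ": ",
                                   conditionMessage(err), call. = FALSE))
    } else if (field == "baseline") {
      fields$baseline <- as.integer(value)
    } else if (field == "link" && length(parts) >= 3L) {
      label <- paste(parts[-(1:2)], collapse = ".")
      fields$links <- c(fields$links, list(list(label = label, url = value)))
    } else if (field == "concepts") {
      fields$concepts <- trimws(strsplit(value, ";", fixed = TRUE)[[1]])
    } else {
      warning("unknown key '", key, "' at line ", i, call. = FALSE)
    }
    grp_sources[[gname]][[src]] <- fields
  }
  if (!is.null(section) && startsWith(section, "group:"))
    flush_group(sub("^group:", "", section))
  monitor_config(groups = groups, sources = sources,
                 cache_interval_days = general$cache_interval_days %||% 7,
                 profiles = general$profiles %||% list(),
                 default_profile = general$default_profile)
}

#' Describe one registered data source
#'
#' @param name source name (unique within its group)
#' @param group provider-group name (one collapsible block in the overview)
#' @param url access-point URI
#' @param filter optional fragment filter (`bcp_filter`)
#' @param baseline_count optional former-period record count for the delta
#'   column
#' @param links list of `list(label=, url=)` useful links
#' @param concept_columns concept paths shown as total/distinct columns
#' @return object of class `data_source`
#' @export
data_source <- function(name, group, url, filter = NULL,
                        baseline_count = NULL, links = list(),
                        concept_columns = character(0)) {
  structure(list(name = name, group = group,
                 endpoint = endpoint(url, default_filter = filter),
                 filter = filter,
                 baseline_count = if (!is.null(baseline_count))
                   as.integer(baseline_count),
                 links = links,
                 concept_columns = vapply(concept_columns, concept_path,
                                          character(1), USE.NAMES = FALSE)),
            class = "data_source")
}

#' @rdname load_config
#' @param groups,sources,cache_interval_days,profiles,default_profile
#'   see return value
#' @export
monitor_config <- function(groups, sources, cache_interval_days = 7,
                           profiles = list(), default_profile = NULL) {
  key <- vapply(sources, function(s) paste(s$group, s$name, sep = "\r"),
                character(1))
  if (anyDuplicated(key)) stop("duplicate (group, source) pair", call. = FALSE)
  for (s in sources)
    if (!s$group %in% groups)
      stop("source '", s$name, "' references unknown group '", s$group, "'",
           call. = FALSE)
  if (cache_interval_days <= 0)
    stop("cache_interval_days must be positive", call. = FALSE)
  if (length(profiles) && !is.null(default_profile) &&
      !default_profile %in% names(profiles))
    stop("default_profile '", default_profile, "' not among profiles",
         call. = FALSE)
  structure(list(groups = groups, sources = sources,
                 cache_interval_days = cache_interval_days,
                 profiles = profiles, default_profile = default_profile),
            class = "monitor_config")
}

#' @export
print.monitor_config <- function(x, ...) {
  cat(sprintf("<monitor config> %d group(s), %d source(s), cache %g day(s)\n",
              length(x$groups), length(x$sources), x$cache_interval_days))
  invisible(x)
}

#' Serialize a configuration back to INI text
#'
#' `load_config(config_to_ini(cfg))` yields a structure equal to `cfg`.
#'
#' @param cfg a `monitor_config`
#' @return INI text
#' @export
config_to_ini <- function(cfg) {
  out <- c("[general]",
           sprintf("cache_interval_days = %g", cfg$cache_interval_days))
  if (!is.null(cfg$default_profile))
    out <- c(out, sprintf("default_profile = %s", cfg$default_profile))
  for (nm in names(cfg$profiles))
    out <- c(out, sprintf("profile.%s = %s", nm, cfg$profiles[[nm]]))
  for (g in cfg$groups) {
    out <- c(out, "", sprintf("[group:%s]", g))
    for (s in cfg$sources) {
      if (s$group != g) next
      out <- c(out, sprintf("%s.url = %s", s$name, s$endpoint$url))
      if (!is.null(s$filter))
        out <- c(out, sprintf("%s.filter = %s", s$name, filter_to_text(s$filter)))
      if (!is.null(s$baseline_count))
        out <- c(out, sprintf("%s.baseline = %d", s$name, s$baseline_count))
      for (lk in s$links)
        out <- c(out, sprintf("%s.link.%s = %s", s$name, lk$label, lk$url))
      if (length(s$concept_columns))
        out <- c(out, sprintf("%s.concepts = %s", s$name,
                              paste(s$concept_columns, collapse = ";")))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Load a target-schema requirement profile
#'
#' Profiles are tab-delimited text with a header row
#' `target_concept<TAB>source_paths<TAB>mandatory<TAB>unique`;
#' `source_paths` holds one or more `;`-separated alternative source
#' concept paths; `mandatory` and `unique` are strict `0`/`1`. Blank lines
#' and `#` comments are skipped.
#'
#' @param text profile text, or use `file`
#' @param file path to a profile file
#' @param name profile name
#' @return object of class `target_profile` with `name` and `rules`
#' @export
load_profile <- function(text = NULL, file = NULL, name = "profile") {
  if (is.null(text)) {
    if (is.null(file)) stop("provide profile text or a file path", call. = FALSE)
    text <- readLines(file, encoding = "UTF-8", warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) return(target_profile(name, list()))
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  expect <- c("target_concept", "source_paths", "mandatory", "unique")
  if (!identical(trimws(header), expect))
    stop("profile header must be: ", paste(expect, collapse = " | "),
         call. = FALSE)
  rules <- list()
  for (i in keep[-1]) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(cells) != 4L)
      stop("profile row at line ", i, " must have 4 tab-separated cells",
           call. = FALSE)
    for (b in cells[3:4])
      if (!trimws(b) %in% c("0", "1"))
        stop("bad boolean '", trimws(b), "' at line ", i,
             " (must be 0 or 1)", call. = FALSE)
    rules[[length(rules) + 1L]] <- list(
      target_concept = trimws(cells[1]),
      source_paths = vapply(trimws(strsplit(cells[2], ";", fixed = TRUE)[[1]]),
                            concept_path, character(1), USE.NAMES = FALSE),
      mandatory = trimws(cells[3]) == "1",
      unique = trimws(cells[4]) == "1")
  }
  target_profile(name, rules)
}

#' @rdname load_profile
#' @param rules list of rule records
#' @export
target_profile <- function(name, rules) {
  targets <- vapply(rules, `[[`, character(1), "target_concept")
  if (anyDuplicated(targets))
    stop("duplicate target_concept in profile '", name, "': ",
         targets[duplicated(targets)][1], call. = FALSE)
  for (r in rules)
    if (length(r$source_paths) < 1L)
      stop("rule for ", r$target_concept, " has no source path", call. = FALSE)
  structure(list(name = name, rules = rules), class = "target_profile")
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target profile> '%s', %d rule(s)\n", x$name, length(x$rules)))
  invisible(x)
}

#' Extract the endpoint from a stand-alone checker URL
#'
#' The mapping checker can be invoked for any data source by passing the
#' source's access point in the `url` query parameter of the service URL.
#' The parameter value is taken verbatim to the end of the string, so an
#' embedded query string of the access point itself (e.g. `?dsa=...`) is
#' preserved; percent-encoded values are decoded once.
#'
#' @param url the checker service URL
#' @return a [endpoint()] for the embedded access point
#' @export
parse_checker_url <- function(url) {
  m <- regexpr("[?&]url=", url)
  if (m == -1L)
    stop("checker URL has no 'url' query parameter: ", url, call. = FALSE)
  value <- substring(url, m + attr(m, "match.length"))
  if (!nzchar(value))
    stop("checker URL has an empty 'url' parameter", call. = FALSE)
  if (grepl("%", value, fixed = TRUE)) value <- utils::URLdecode(value)
  endpoint(value)
}
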