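#' @title Synthetic provider: offline data source and counting oracle
#' @description
#' A synthetic provider emulates a wrapped collection database: an
#' in-memory table of unit records drawn deterministically from per-concept
#' value pools, dataset-level metadata, and rule-driven value dropping.
#' A dropped value is one present in the source table but absent from the
#' served responses; the four reasons mirror what provider middleware does
#' in practice: a mandatory value missing, a parent element missing at a
#' higher hierarchy level, an invalid value (e.g. wrong character
#' encoding), or a value outside the schema's permitted list.
#'
#' The provider keeps both views: `table` (ground truth, pre-drop) and
#' `delivered` (post-drop, what requests see), plus a `drop_ledger`
#' counting dropped occurrences per concept and reason, and a
#' `request_log` of every request served. [oracle_stats()] computes
#' counting statistics by brute force directly on these views, independent
#' of the request/response code path, and is the ground truth all client
#' statistics are tested against.
#' @name provider
NULL

#' Describe one concept of a provider spec
#'
#' @param path concept path
#' @param searchable logical; whether the concept maps an atomized,
#'   filterable database field
#' @param datatype one of `string`, `integer`, `decimal`, `date`, `uri`
#' @param value_pool character vector the generator draws values from
#' @param multiplicity `single` (one value per record) or `multi`
#'   (1-3 values per record)
#' @param presence probability in (0, 1] that a record carries the concept
#' @param distinct_values draw without replacement so no two records share
#'   a value (for identifier concepts such as the unit inventory number);
#'   requires a pool at least as large as `n_records`, single
#'   multiplicity and presence 1
#' @return list describing the concept
#' @export
spec_concept <- function(path, searchable = TRUE, datatype = "string",
                         value_pool = character(0),
                         multiplicity = c("single", "multi"),
                         presence = 1.0, distinct_values = FALSE) {
  datatype <- match.arg(datatype, c("string", "integer", "decimal", "date", "uri"))
  stopifnot(presence > 0, presence <= 1)
  multiplicity <- match.arg(multiplicity)
  if (isTRUE(distinct_values) && (multiplicity != "single" || presence < 1))
    stop("distinct_values requires single multiplicity and presence 1",
         call. = FALSE)
  list(path = concept_path(path), searchable = isTRUE(searchable),
       datatype = datatype, value_pool = as.character(value_pool),
       multiplicity = multiplicity, presence = presence,
       distinct_values = isTRUE(distinct_values))
}

#' Describe a value-dropping rule
#'
#' A rule drops matching value occurrences of one concept from the served
#' view and ledgers them under its reason. When a rule empties a concept's
#' values in a record and other mapped concepts are hierarchical children
#' of that path, their occurrences in the record are dropped too and
#' ledgered under `parent_missing`.
#'
#' @param concept concept path the rule applies to
#' @param reason one of `missing_mandatory`, `parent_missing`,
#'   `invalid_encoding`, `outside_value_list`
#' @param values literal set of values to drop (exact match), or
#' @param pattern a `*`-wildcard pattern to drop
#' @return list describing the rule
#' @export
drop_rule <- function(concept, reason, values = NULL, pattern = NULL) {
  reason <- match.arg(reason, DROP_REASONS)
  if (is.null(values) && is.null(pattern))
    stop("drop rule needs a literal value set or a wildcard pattern",
         call. = FALSE)
  list(concept = concept_path(concept), reason = reason,
       values = values, pattern = pattern)
}

#' Build a provider spec
#'
#' @param concepts list of [spec_concept()] entries; paths must be unique
#' @param n_records number of unit records (>= 1)
#' @param dataset_meta named list, concept path -> string (dataset-level
#'   metadata such as collection title)
#' @param seed integer seed; equal (spec, seed) gives byte-identical tables
#' @param drop_rules list of [drop_rule()] entries
#' @param repeat_dataset_per_unit emulate the normalization defect where
#'   dataset metadata is repeated once per unit in search responses
#' @param last_modified optional ISO-8601 date stamped on responses
#' @return object of class `provider_spec`
#' @export
provider_spec <- function(concepts, n_records, dataset_meta = list(),
                          seed = 1L, drop_rules = list(),
                          repeat_dataset_per_unit = FALSE,
                          last_modified = NULL) {
  paths <- vapply(concepts, `[[`, character(1), "path")
  if (anyDuplicated(paths)) stop("concept paths must be unique", call. = FALSE)
  if (n_records < 1) stop("n_records must be >= 1", call. = FALSE)
  for (cc in concepts)
    if (length(cc$value_pool) == 0L && cc$presence >= 1)
      stop("empty value_pool for always-present concept ", cc$path, call. = FALSE)
  structure(list(concepts = concepts, n_records = as.integer(n_records),
                 dataset_meta = dataset_meta, seed = as.integer(seed),
                 drop_rules = drop_rules,
                 repeat_dataset_per_unit = isTRUE(repeat_dataset_per_unit),
                 last_modified = last_modified),
            class = "provider_spec")
}

# run code under a local RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

rule_matches <- function(rule, value) {
  if (!is.null(rule$values)) value %in% rule$values
  else like_match(value, rule$pattern)
}

#' Instantiate a synthetic provider from a spec
#'
#' Deterministic for equal (spec, seed). Values are drawn from each
#' concept's value pool; drop rules are then applied to produce the
#' delivered view and populate the drop ledger.
#'
#' @param spec a [provider_spec()]
#' @return object of class `synthetic_provider` (an environment holding
#'   `spec`, `table`, `delivered`, `drop_ledger`, `request_log`)
#' @export
make_provider <- function(spec) {
  stopifnot(inherits(spec, "provider_spec"))
  table <- with_local_seed(spec$seed, {
    assigned <- list()  # per-concept permutation for distinct_values draws
    for (cc in spec$concepts) {
      if (!isTRUE(cc$distinct_values)) next
      if (length(cc$value_pool) < spec$n_records)
        stop("value_pool of ", cc$path, " too small for ", spec$n_records,
             " distinct values", call. = FALSE)
      assigned[[cc$path]] <- sample(cc$value_pool, spec$n_records)
    }
    lapply(seq_len(spec$n_records), function(i) {
      vals <- list()
      for (cc in spec$concepts) {
        if (!is.null(assigned[[cc$path]])) {
          vals[[cc$path]] <- assigned[[cc$path]][i]
          next
        }
        if (cc$presence < 1 && stats::runif(1) > cc$presence) next
        if (length(cc$value_pool) == 0L) next
        k <- if (cc$multiplicity == "multi") sample.int(3L, 1L) else 1L
        vals[[cc$path]] <- sample(cc$value_pool, k, replace = TRUE)
      }
      unit_record(sprintf("unit%05d", i), vals)
    })
  })
  concept_paths <- vapply(spec$concepts, `[[`, character(1), "path")
  ledger <- new.env(parent = emptyenv())
  drop_count <- function(path, reason, n) {
    key <- paste(path, reason, sep = "\r")
    assign(key, (if (exists(key, ledger)) get(key, ledger) else 0L) + n, ledger)
  }
  delivered <- lapply(table, function(r) {
    vals <- r$values
    for (rule in spec$drop_rules) {
      v <- vals[[rule$concept]]
      if (is.null(v)) next
      hit <- vapply(v, rule_matches, logical(1), rule = rule)
      if (!any(hit)) next
      drop_count(rule$concept, rule$reason, sum(hit))
      kept <- v[!hit]
      if (length(kept)) {
        vals[[rule$concept]] <- kept
      } else {
        vals[[rule$concept]] <- NULL
        # parent now absent in this record: dependent children go with it
        kids <- concept_paths[startsWith(concept_paths,
                                         paste0(rule$concept, "/"))]
        for (kid in kids) {
          kv <- vals[[kid]]
          if (is.null(kv)) next
          drop_count(kid, "parent_missing", length(kv))
          vals[[kid]] <- NULL
        }
      }
    }
    if (length(vals)) unit_record(r$unit_id, vals)
    else structure(list(unit_id = r$unit_id, values = list()),
                   class = "unit_record")
  })
  ledger_df <- if (length(ls(ledger))) {
    keys <- sort(ls(ledger))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(concept = vapply(parts, `[[`, character(1), 1L),
               reason = vapply(parts, `[[`, character(1), 2L),
               count = vapply(keys, function(k) get(k, ledger), integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(concept = character(0), reason = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  p <- new.env(parent = emptyenv())
  p$spec <- spec
  p$table <- table
  p$delivered <- delivered
  p$drop_ledger <- ledger_df
  p$request_log <- list()
  class(p) <- "synthetic_provider"
  p
}

#' @export
print.synthetic_provider <- function(x, ...) {
  cat(sprintf("<synthetic provider> %d records, %d concepts, %d requests served\n",
              length(x$table), length(x$spec$concepts), length(x$request_log)))
  invisible(x)
}

provider_concept <- function(p, path) {
  for (cc in p$spec$concepts) if (cc$path == path) return(cc)
  NULL
}

# occurrences of `path` in record r (a unit_record), integer
occ_count <- function(r, path) {
  v <- r$values[[path]]
  if (is.null(v)) 0L else length(v)
}

matching_idx <- function(records, filter) {
  if (is.null(filter)) seq_along(records)
  else which(vapply(records, function(r) evaluate_filter(filter, r), logical(1)))
}

#' Serve one protocol request
#'
#' Applies the request to the provider's delivered view: capabilities
#' reflect the spec's concepts and flags; search evaluates the filter
#' against delivered values and pages the matches; scan returns the sorted
#' distinct delivered values of the concept. Search pages carry
#' drop-report diagnostics (code `droppedValue`) whenever served records
#' omitted table values. If the spec sets `repeat_dataset_per_unit`, the
#' search response repeats the dataset metadata block once per unit served.
#' The request is appended to the provider's `request_log`.
#'
#' @param p a `synthetic_provider`
#' @param req a [bcp_request()]
#' @return a `bcp_response`
#' @export
handle_request <- function(p, req) {
  stopifnot(inherits(p, "synthetic_provider"), inherits(req, "bcp_request"))
  p$request_log <- c(p$request_log, list(req))
  last_mod <- p$spec$last_modified
  if (req$kind == "capabilities") {
    caps <- capabilities_report(lapply(p$spec$concepts, function(cc)
      list(path = cc$path, searchable = cc$searchable, datatype = cc$datatype)))
    return(new_response("capabilities", capabilities = caps,
                        last_modified = last_mod))
  }
  if (req$kind == "scan") {
    cc <- provider_concept(p, req$concept)
    if (is.null(cc)) {
      return(new_response("scan", values = NULL, diagnostics = list(
        bcp_diagnostic("error", "unmappedConcept",
                       paste0("concept not mapped: ", req$concept)))))
    }
    idx <- matching_idx(p$delivered, req$filter)
    vals <- unlist(lapply(p$delivered[idx], function(r) r$values[[req$concept]]),
                   use.names = FALSE)
    vals <- sort(unique(vals %||% character(0)), method = "radix")
    return(new_response("scan", values = vals, last_modified = last_mod))
  }
  # search
  idx <- matching_idx(p$delivered, req$filter)
  n <- length(idx)
  if (req$count_only) {
    return(new_response("search", record_count = n,
                        dataset_meta = p$spec$dataset_meta,
                        n_dataset_blocks = if (length(p$spec$dataset_meta)) 1L else 0L,
                        last_modified = last_mod))
  }
  start <- req$start %||% 0L
  limit <- req$limit %||% n
  page_idx <- idx[idx_window(n, start, limit)]
  served <- p$delivered[page_idx]
  # drop-report diagnostics for the served page: table minus delivered
  diags <- list()
  if (length(page_idx)) {
    for (cc in p$spec$concepts) {
      dropped <- sum(vapply(page_idx, function(i)
        occ_count(p$table[[i]], cc$path) - occ_count(p$delivered[[i]], cc$path),
        integer(1)))
      if (dropped > 0L)
        diags <- c(diags, list(bcp_diagnostic("warning", DROP_DIAG_CODE,
          paste0(dropped, " value(s) of ", cc$path,
                 " present in the database but absent from the response"),
          concept = cc$path, count = dropped)))
    }
  }
  n_blocks <- if (!length(p$spec$dataset_meta)) 0L
              else if (p$spec$repeat_dataset_per_unit) max(length(served), 1L)
              else 1L
  new_response("search", record_count = n, records = served,
               diagnostics = diags, dataset_meta = p$spec$dataset_meta,
               n_dataset_blocks = n_blocks, last_modified = last_mod)
}

idx_window <- function(n, start, limit) {
  if (start >= n) integer(0) else seq.int(start + 1L, min(n, start + limit))
}

#' Brute-force counting oracle
#'
#' Computes per-concept statistics directly from the provider's table and
#' delivered views, bypassing the request/response path entirely:
#' `total` = delivered value occurrences of the concept across matching
#' records, `distinct` = number of unique delivered values, `dropped` =
#' table-minus-delivered occurrence difference across matching records.
#' Matching is evaluated on delivered values, as a real client would see
#' them.
#'
#' @param p a `synthetic_provider`
#' @param concept concept path
#' @param filter optional `bcp_filter`
#' @return a [concept_stats_row()]
#' @export
oracle_stats <- function(p, concept, filter = NULL) {
  stopifnot(inherits(p, "synthetic_provider"))
  idx <- matching_idx(p$delivered, filter)
  vals <- unlist(lapply(p$delivered[idx], function(r) r$values[[concept]]),
                 use.names = FALSE) %||% character(0)
  dropped <- sum(vapply(idx, function(i)
    occ_count(p$table[[i]], concept) - occ_count(p$delivered[[i]], concept),
    integer(1)))
  concept_stats_row(concept, total = length(vals),
                    distinct = length(unique(vals)), dropped = dropped)
}

#' Oracle record count
#'
#' Number of delivered records matching the filter, computed by brute
#' force on the provider table.
#'
#' @inheritParams oracle_stats
#' @return non-negative integer
#' @export
oracle_count <- function(p, filter = NULL) length(matching_idx(p$delivered, filter))

#' Read or write a provider spec as JSON
#'
#' The JSON layout mirrors [provider_spec()]: fields `concepts` (array of
#' objects with `path`, `searchable`, `datatype`, `value_pool`,
#' `multiplicity`, `presence`), `n_records`, `dataset_meta`, `seed`,
#' `drop_rules` (objects with `concept`, `reason`, and `values` or
#' `pattern`) and `repeat_dataset_per_unit`.
#'
#' @param path file path
#' @return `read_provider_spec()`: a `provider_spec`
#' @export
read_provider_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  concepts <- lapply(x$concepts, function(cc)
    spec_concept(cc$path, searchable = isTRUE(cc$searchable),
                 datatype = cc$datatype %||% "string",
                 value_pool = unlist(cc$value_pool) %||% character(0),
                 multiplicity = cc$multiplicity %||% "single",
                 presence = cc$presence %||% 1.0,
                 distinct_values = isTRUE(cc$distinct_values)))
  rules <- lapply(x$drop_rules %||% list(), function(rr)
    drop_rule(rr$concept, rr$reason,
              values = if (!is.null(rr$values)) unlist(rr$values),
              pattern = rr$pattern))
  provider_spec(concepts, n_records = x$n_records,
                dataset_meta = lapply(x$dataset_meta %||% list(), as.character),
                seed = x$seed %||% 1L, drop_rules = rules,
                repeat_dataset_per_unit = isTRUE(x$repeat_dataset_per_unit),
                last_modified = x$last_modified)
}

#' @rdname read_provider_spec
#' @param spec a `provider_spec`
#' @export
write_provider_spec <- function(spec, path) {
  x <- unclass(spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
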