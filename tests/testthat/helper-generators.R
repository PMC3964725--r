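# Seeded random generators for property-style tests. All randomness goes
# through a local RNG stream so tests are reproducible and do not disturb
# the session RNG.

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

rand_path <- function(depth = sample(2:4, 1)) {
  segs <- replicate(depth, paste(sample(letters, sample(3:6, 1),
                                        replace = TRUE), collapse = ""))
  paste0("/", paste(segs, collapse = "/"))
}

# small shared path universe so filters and records actually interact
PATH_POOL <- c("/ds/unit/id", "/ds/unit/name", "/ds/unit/country",
               "/ds/unit/uri", "/ds/unit/depth", "/ds/meta/title")
VALUE_POOL <- c("Abies alba", "Fagus", "Mus musculus", "", "10", "9", "2.5",
                "Germany", "Aus*tria", "café", "a&b<c>", "zz")

rand_filter <- function(depth = 3) {
  kind <- if (depth <= 0) sample(c("cmp", "null"), 1)
          else sample(c("cmp", "null", "not", "and", "or"), 1,
                      prob = c(0.3, 0.2, 0.15, 0.2, 0.15))
  path <- sample(PATH_POOL, 1)
  switch(kind,
    cmp = flt_cmp(sample(c("equals", "like", "lessThan", "lessThanOrEquals",
                           "greaterThan", "greaterThanOrEquals"), 1),
                  path, sample(c(VALUE_POOL, "Mus*", "*a", "1*"), 1)),
    null = if (stats::runif(1) < 0.5) flt_is_null(path) else flt_is_not_null(path),
    not = flt_not(rand_filter(depth - 1)),
    and = flt_junction("and", replicate(sample(1:3, 1),
                                        rand_filter(depth - 1),
                                        simplify = FALSE)),
    or = flt_junction("or", replicate(sample(1:3, 1),
                                      rand_filter(depth - 1),
                                      simplify = FALSE)))
}

rand_record <- function(i = 1) {
  paths <- sample(PATH_POOL, sample(0:length(PATH_POOL), 1))
  vals <- lapply(paths, function(p)
    sample(VALUE_POOL, sample(1:3, 1), replace = TRUE))
  names(vals) <- paths
  unit_record(sprintf("u%04d", i), vals)
}

rand_request <- function() {
  kind <- sample(c("capabilities", "search", "scan"), 1)
  switch(kind,
    capabilities = bcp_request("capabilities"),
    search = bcp_request("search",
                         filter = if (stats::runif(1) < 0.7) rand_filter(),
                         count_only = stats::runif(1) < 0.3,
                         start = sample(0:20, 1), limit = sample(1:50, 1)),
    scan = bcp_request("scan", concept = sample(PATH_POOL, 1),
                       filter = if (stats::runif(1) < 0.5) rand_filter()))
}

# random synthetic provider spec within the study envelope:
# <= 200 records, <= 8 concepts, random drop rules
rand_provider_spec <- function(max_records = 200, max_concepts = 8) {
  n_concepts <- sample(1:max_concepts, 1)
  concepts <- lapply(seq_len(n_concepts), function(j)
    spec_concept(PATH_POOL[j %% length(PATH_POOL) + 1L],
                 searchable = stats::runif(1) < 0.8,
                 datatype = sample(c("string", "integer", "uri"), 1),
                 value_pool = sample(VALUE_POOL, sample(2:8, 1)),
                 multiplicity = sample(c("single", "multi"), 1,
                                       prob = c(0.7, 0.3)),
                 presence = sample(c(1, 1, 0.8, 0.5), 1)))
  # concept paths must be unique
  keep <- !duplicated(vapply(concepts, `[[`, character(1), "path"))
  concepts <- concepts[keep]
  rules <- list()
  if (stats::runif(1) < 0.6) {
    n_rules <- sample(1:2, 1)
    for (k in seq_len(n_rules)) {
      cc <- concepts[[sample(length(concepts), 1)]]
      if (!length(cc$value_pool)) next
      rules[[length(rules) + 1L]] <- drop_rule(
        cc$path, sample(DROP_REASONS_TEST, 1),
        values = sample(cc$value_pool, sample(1:2, 1)))
    }
  }
  provider_spec(concepts, n_records = sample(5:max_records, 1),
                dataset_meta = list("/ds/meta/title" = "Synthetic collection"),
                seed = sample.int(1e6, 1), drop_rules = rules,
                repeat_dataset_per_unit = FALSE,
                last_modified = "2026-01-15")
}

DROP_REASONS_TEST <- c("missing_mandatory", "parent_missing",
                       "invalid_encoding", "outside_value_list")

# provider + endpoint + transport bundle
rand_rig <- function(...) {
  p <- make_provider(rand_provider_spec(...))
  url <- "mock://rig"
  list(p = p, e = endpoint(url), tr = mock_transport(stats::setNames(list(p), url)))
}

extdata <- function(...) system.file("extdata", ..., package = "biocasemon")

# the worked FileURI fixture: one URI shared by two of ten records, all
# other URIs unique -> total 10, distinct 9
fileuri_provider <- function() {
  uri_path <- "/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI"
  id_path <- "/DataSets/DataSet/Units/Unit/UnitID"
  uris <- c(sprintf("http://img.example.org/%02d.jpg", 1:9),
            "http://img.example.org/01.jpg")
  recs <- lapply(1:10, function(i)
    unit_record(sprintf("u%02d", i),
                stats::setNames(list(sprintf("ID-%02d", i), uris[i]),
                                c(id_path, uri_path))))
  spec <- provider_spec(
    list(spec_concept(id_path, value_pool = sprintf("ID-%02d", 1:10),
                      distinct_values = TRUE),
         spec_concept(uri_path, searchable = FALSE, datatype = "uri",
                      value_pool = uris)),
    n_records = 10, seed = 1)
  p <- make_provider(spec)
  # pin the exact table: generator randomness must not decide this fixture
  p$table <- recs
  p$delivered <- recs
  p$drop_ledger <- p$drop_ledger[0, ]
  p
}
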