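t0 <- as.POSIXct("2026-03-01 12:00:00", tz = "UTC")

# three mock sources behind the shipped example config
monitor_rig <- function(down = character(0)) {
  herbar <- make_provider(read_provider_spec(extdata("provider-herbar.json")))
  palfish <- make_provider(read_provider_spec(extdata("provider-palfish.json")))
  cfg <- load_config(file = extdata("monitor.ini"))
  list(cfg = cfg,
       herbar = herbar, palfish = palfish,
       tr = mock_transport(list("mock://herbar" = herbar,
                                "mock://palfish" = palfish), down = down))
}

request_count <- function(rig) length(rig$herbar$request_log) +
  length(rig$palfish$request_log)

test_that("the overview has one row per source, in config order, with
           oracle-exact counts", {
  rig <- monitor_rig()
  o <- build_overview(rig$cfg, rig$tr, now = t0)
  rows <- biocasemon:::overview_rows(o)
  expect_length(rows, 3L)
  expect_identical(names(o$groups), c("Herbaria", "Paleontology"))
  expect_identical(unname(vapply(rows, function(r) r$source$name,
                                 character(1))),
                   c("herbar", "algae", "palfish"))
  expect_identical(rows[[1]]$record_count, oracle_count(rig$herbar))
  expect_identical(rows[[2]]$record_count,
                   oracle_count(rig$herbar, rig$cfg$sources[[2]]$filter))
  expect_identical(rows[[3]]$record_count, oracle_count(rig$palfish))
  uri <- rig$cfg$sources[[1]]$concept_columns[[1]]
  expect_identical(unclass(rows[[1]]$concept_stats[[uri]]),
                   unclass(oracle_stats(rig$herbar, uri)))
  expect_identical(rows[[1]]$last_modified, "2026-08-30")
})

test_that("baseline deltas are signed differences and antisymmetric", {
  rig <- monitor_rig()
  o <- build_overview(rig$cfg, rig$tr, now = t0)
  row <- biocasemon:::overview_rows(o)[[1]]
  expect_identical(row$delta, row$record_count - 10L)
  # antisymmetry: swapping baseline and current negates the delta
  expect_identical(row$record_count - 10L, -(10L - row$record_count))
})

test_that("a down source yields an unreachable row and never aborts the
           build", {
  rig <- monitor_rig(down = "mock://palfish")
  o <- build_overview(rig$cfg, rig$tr, now = t0)
  rows <- biocasemon:::overview_rows(o)
  expect_identical(unname(vapply(rows, `[[`, character(1), "status")),
                   c("ok", "ok", "unreachable"))
  expect_null(rows[[3]]$record_count)
})

test_that("a warm cache serves a full rebuild with zero transport calls;
           renew forces a refetch of just that source", {
  rig <- monitor_rig()
  cache <- file_cache(withr::local_tempdir())
  o1 <- build_overview(rig$cfg, rig$tr, cache = cache, now = t0)
  warm <- request_count(rig)
  expect_gt(warm, 0L)
  o2 <- build_overview(rig$cfg, rig$tr, cache = cache, now = t0 + 3600)
  expect_identical(request_count(rig), warm)   # zero new requests
  expect_identical(export_tsv(o2), export_tsv(o1))
  # entries older than the interval are re-fetched
  build_overview(rig$cfg, rig$tr, cache = cache, now = t0 + 8 * 86400)
  expect_gt(request_count(rig), warm)
  # manual renew re-fetches the named source even inside the window
  n <- request_count(rig)
  build_overview(rig$cfg, rig$tr, cache = cache, now = t0 + 8 * 86400 + 60,
                 renew = "herbar")
  expect_gt(length(rig$herbar$request_log), 0L)
  expect_gt(request_count(rig), n)
})

test_that("an unreachable verdict is cached briefly and does not poison
           fresh result entries", {
  rig <- monitor_rig()
  cache <- file_cache(withr::local_tempdir())
  build_overview(rig$cfg, rig$tr, cache = cache, now = t0)
  warm <- request_count(rig)
  down <- monitor_rig(down = "mock://palfish")
  # palfish results are still fresh in cache, so the outage is invisible
  o <- build_overview(down$cfg, down$tr, cache = cache, now = t0 + 3600)
  expect_true(all(vapply(biocasemon:::overview_rows(o), `[[`, character(1),
                         "status") == "ok"))
})

test_that("TSV export follows the documented column contract and parses
           back to the overview's values", {
  rig <- monitor_rig()
  o <- build_overview(rig$cfg, rig$tr, now = t0)
  tsv <- export_tsv(o)
  expect_true(endsWith(tsv, "\n"))
  lines <- strsplit(tsv, "\n", fixed = TRUE)[[1]]
  expect_length(lines, 4L)   # header + three sources
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expect_identical(header[1:8],
                   c("group", "name", "endpoint", "status", "records",
                     "last_modified", "delta", "links"))
  # two configured concept columns -> two total/distinct pairs
  expect_length(header, 8L + 2L * 2L)
  df <- parse_overview_tsv(tsv)
  expect_identical(df$name, c("herbar", "algae", "palfish"))
  expect_identical(df$records,
                   as.character(vapply(biocasemon:::overview_rows(o),
                                       `[[`, integer(1), "record_count")))
  uri <- rig$cfg$sources[[1]]$concept_columns[[1]]
  st <- biocasemon:::overview_rows(o)[[1]]$concept_stats[[uri]]
  expect_identical(df[[paste0(uri, ".total")]][1], as.character(st$total))
  expect_identical(df[[paste0(uri, ".distinct")]][1],
                   as.character(st$distinct))
})

test_that("the shared-FileURI fixture shows distinct = total - 1 in the
           export", {
  p <- fileuri_provider()
  uri <- "/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI"
  cfg <- monitor_config(groups = "G",
    sources = list(data_source("media", "G", "mock://uri",
                               concept_columns = uri)))
  o <- build_overview(cfg, mock_transport(list("mock://uri" = p)), now = t0)
  df <- parse_overview_tsv(export_tsv(o))
  expect_identical(df[[paste0(uri, ".total")]], "10")
  expect_identical(df[[paste0(uri, ".distinct")]], "9")
})

test_that("HTML output has one section per group and renders links as
           anchors with their labels", {
  rig <- monitor_rig()
  o <- build_overview(rig$cfg, rig$tr, now = t0)
  html <- render_overview(o, "html")
  expect_identical(lengths(regmatches(html,
    gregexpr('<section class="group"', html, fixed = TRUE))), 2L)
  expect_match(html, '<a href="http://data.example.org/datasets/resource/14719">portal</a>',
               fixed = TRUE)
  expect_error(render_overview(o, "pdf"))
})

test_that("JSON rendering round-trips to an equal overview", {
  rig <- monitor_rig()
  o <- build_overview(rig$cfg, rig$tr, now = t0)
  back <- parse_overview_json(render_overview(o, "json"))
  expect_identical(export_tsv(back), export_tsv(o))
  expect_equal(back$cache_interval_days, o$cache_interval_days)
  expect_identical(format(back$generated_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   format(o$generated_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
})
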