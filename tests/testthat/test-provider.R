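mini_spec <- function(drop_rules = list(), n = 10, repeat_ds = FALSE,
                      seed = 5) {
  provider_spec(
    list(spec_concept("/ds/unit/id", value_pool = sprintf("id%03d", 1:100),
                      distinct_values = TRUE),
         spec_concept("/ds/unit/name",
                      value_pool = c("Abies alba", "Fagus", "Picea")),
         spec_concept("/ds/unit/name/auth", value_pool = c("L.", "Mill.")),
         spec_concept("/ds/unit/uri", searchable = FALSE, datatype = "uri",
                      value_pool = c("u1", "u2", "u3"),
                      multiplicity = "multi", presence = 0.8)),
    n_records = n, dataset_meta = list("/ds/meta/title" = "T"),
    seed = seed, drop_rules = drop_rules,
    repeat_dataset_per_unit = repeat_ds, last_modified = "2026-02-02")
}

test_that("equal (spec, seed) gives identical tables; the session RNG is
           untouched", {
  set.seed(99)
  before <- get(".Random.seed", envir = globalenv())
  p1 <- make_provider(mini_spec())
  expect_identical(get(".Random.seed", envir = globalenv()), before)
  p2 <- make_provider(mini_spec())
  expect_identical(p1$table, p2$table)
  expect_identical(p1$delivered, p2$delivered)
  p3 <- make_provider(mini_spec(seed = 6))
  expect_false(identical(p1$table, p3$table))
})

test_that("a minimal one-record spec builds a one-row table", {
  p <- make_provider(provider_spec(
    list(spec_concept("/p", value_pool = "x")), n_records = 1))
  expect_length(p$table, 1L)
  expect_identical(p$table[[1]]$values[["/p"]], "x")
})

test_that("an always-present concept with an empty pool is a spec error", {
  expect_error(provider_spec(list(spec_concept("/p")), n_records = 2),
               "empty value_pool")
})

test_that("drop rules ledger exactly the matching occurrences", {
  rule <- drop_rule("/ds/unit/name", "invalid_encoding", values = "Fagus")
  p <- make_provider(mini_spec(drop_rules = list(rule), n = 50))
  expected <- sum(vapply(p$table, function(r)
    sum(r$values[["/ds/unit/name"]] == "Fagus"), integer(1)))
  got <- p$drop_ledger[p$drop_ledger$concept == "/ds/unit/name" &
                       p$drop_ledger$reason == "invalid_encoding", "count"]
  expect_gt(expected, 0L)
  expect_identical(sum(got), expected)
  # delivered view no longer contains the dropped value
  expect_false(any(vapply(p$delivered, function(r)
    "Fagus" %in% (r$values[["/ds/unit/name"]] %||% character(0)),
    logical(1))))
})

test_that("emptying a parent's values cascades to hierarchical children,
           ledgered under parent_missing", {
  rules <- list(drop_rule("/ds/unit/name", "missing_mandatory",
                          values = c("Abies alba", "Fagus", "Picea")))
  p <- make_provider(mini_spec(drop_rules = rules, n = 30))
  # every name is dropped, so every author occurrence loses its parent
  auth_table <- sum(vapply(p$table, function(r)
    length(r$values[["/ds/unit/name/auth"]] %||% character(0)), integer(1)))
  led <- p$drop_ledger
  expect_identical(
    sum(led[led$concept == "/ds/unit/name/auth" &
            led$reason == "parent_missing", "count"]),
    auth_table)
  expect_true(all(vapply(p$delivered, function(r)
    is.null(r$values[["/ds/unit/name/auth"]]), logical(1))))
})

test_that("conservation: delivered occurrences plus ledger equal table
           occurrences for every concept, across random providers", {
  with_seed(301, {
    for (i in 1:30) {
      p <- make_provider(rand_provider_spec(max_records = 60))
      for (cc in p$spec$concepts) {
        tab <- sum(vapply(p$table, biocasemon:::occ_count, integer(1),
                          path = cc$path))
        del <- sum(vapply(p$delivered, biocasemon:::occ_count, integer(1),
                          path = cc$path))
        led <- sum(p$drop_ledger[p$drop_ledger$concept == cc$path, "count"])
        expect_identical(del + led, tab)
      }
    }
  })
})

test_that("search responses count delivered matches and page correctly", {
  p <- make_provider(mini_spec(n = 25))
  resp <- handle_request(p, bcp_request("search", count_only = TRUE))
  expect_identical(resp$record_count, 25L)
  expect_null(resp$records)
  page <- handle_request(p, bcp_request("search", start = 20, limit = 10))
  expect_length(page$records, 5L)
  expect_identical(page$record_count, 25L)
})

test_that("scan returns sorted distinct delivered values; unmapped concepts
           yield an error diagnostic in the response", {
  p <- make_provider(mini_spec(n = 40))
  resp <- handle_request(p, bcp_request("scan", concept = "/ds/unit/name"))
  expect_identical(resp$values, sort(unique(unlist(lapply(p$delivered,
    function(r) r$values[["/ds/unit/name"]]))), method = "radix"))
  bad <- handle_request(p, bcp_request("scan", concept = "/nope"))
  expect_identical(bad$diagnostics[[1]]$level, "error")
})

test_that("repeat_dataset_per_unit repeats the metadata block once per
           served unit", {
  p <- make_provider(mini_spec(n = 7, repeat_ds = TRUE))
  resp <- handle_request(p, bcp_request("search", start = 0, limit = 100))
  expect_identical(resp$n_dataset_blocks, 7L)
  doc <- xml2::read_xml(build_response(resp))
  expect_length(xml2::xml_find_all(doc, "//datasetMeta"), 7L)
  pn <- make_provider(mini_spec(n = 7, repeat_ds = FALSE))
  expect_identical(handle_request(pn, bcp_request("search", start = 0,
                                                  limit = 100))$n_dataset_blocks,
                   1L)
})

test_that("replaying a request log reproduces identical responses", {
  with_seed(302, {
    p <- make_provider(rand_provider_spec(max_records = 40))
    reqs <- replicate(10, rand_request(), simplify = FALSE)
    first <- lapply(reqs, function(q) build_response(handle_request(p, q)))
    replay <- lapply(p$request_log, function(q)
      build_response(handle_request(p, q)))
    expect_identical(replay[seq_along(first)], first)
  })
})

test_that("oracle extremes: all-dropped concepts and rule-free specs", {
  all_drop <- drop_rule("/ds/unit/name", "outside_value_list",
                        pattern = "*")
  p <- make_provider(mini_spec(drop_rules = list(all_drop), n = 15))
  st <- oracle_stats(p, "/ds/unit/name")
  tab <- sum(vapply(p$table, biocasemon:::occ_count, integer(1),
                    path = "/ds/unit/name"))
  expect_identical(st$total, 0L)
  expect_identical(st$dropped, tab)
  pclean <- make_provider(mini_spec(n = 15))
  for (cc in pclean$spec$concepts)
    expect_identical(oracle_stats(pclean, cc$path)$dropped, 0L)
})

test_that("provider specs round-trip through their JSON file form", {
  spec <- mini_spec(drop_rules = list(
    drop_rule("/ds/unit/name", "invalid_encoding", values = "Fagus")))
  f <- withr::local_tempfile(fileext = ".json")
  write_provider_spec(spec, f)
  back <- read_provider_spec(f)
  expect_identical(make_provider(back)$table, make_provider(spec)$table)
  expect_identical(back$repeat_dataset_per_unit, spec$repeat_dataset_per_unit)
})
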