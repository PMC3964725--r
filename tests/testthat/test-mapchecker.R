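uri_path <- "/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI"
id_path <- "/DataSets/DataSet/Units/Unit/UnitID"
name_path <- paste0("/DataSets/DataSet/Units/Unit/Identifications/",
                    "Identification/Result/TaxonIdentified/ScientificName/",
                    "FullScientificNameString")

# a provider whose mapping is fully compliant with the default profile
clean_spec <- function(n = 10, seed = 21, drop_rules = list(),
                       repeat_ds = FALSE) {
  provider_spec(
    list(spec_concept(id_path, value_pool = sprintf("ID-%03d", 1:200),
                      distinct_values = TRUE),
         spec_concept(name_path, value_pool = c("Abies alba", "Fagus sylvatica",
                                                "Picea abies")),
         spec_concept(uri_path, value_pool = sprintf("http://img/%d.jpg", 1:50)),
         spec_concept("/DataSets/DataSet/Units/Unit/Gathering/LocalityText",
                      value_pool = c("Berlin", "Wien")),
         spec_concept("/DataSets/DataSet/Metadata/Description/Representation/Title",
                      value_pool = "Collection title")),
    n_records = n, seed = seed, drop_rules = drop_rules,
    dataset_meta = list("/DataSets/DataSet/Metadata/Description/Representation/Title" = "T"),
    repeat_dataset_per_unit = repeat_ds)
}

rig_for <- function(spec) {
  p <- make_provider(spec)
  list(p = p, e = endpoint("mock://src"),
       tr = mock_transport(list("mock://src" = p)))
}

default_profile <- load_profile(file = extdata("profiles", "default.tsv"),
                                name = "default")

test_that("the report has one row per mapped concept, carrying stats,
           samples and resolved target concepts", {
  rig <- rig_for(clean_spec())
  rep <- build_mapping_report(rig$e, rig$tr, default_profile)
  expect_length(rep$rows, 5L)
  expect_setequal(vapply(rep$rows, `[[`, character(1), "path"),
                  vapply(rig$p$spec$concepts, `[[`, character(1), "path"))
  id_row <- Filter(function(r) r$path == id_path, rep$rows)[[1]]
  expect_identical(id_row$target_concept, "dc:identifier")
  expect_identical(unclass(id_row$stats), unclass(oracle_stats(rig$p, id_path)))
  expect_identical(id_row$constraint_notes,
                   c("mandatory in target schema",
                     "must be unique in target schema"))
  expect_length(id_row$samples, 5L)   # default sample_size
})

test_that("samples come from the first records and respect sample_size and
           short sources", {
  rig <- rig_for(clean_spec(n = 3))
  rep <- build_mapping_report(rig$e, rig$tr, default_profile, sample_size = 5)
  for (row in rep$rows)
    expect_lte(length(row$samples), 3L)
  first_vals <- rig$p$delivered[[1]]$values[[id_path]]
  rep2 <- build_mapping_report(rig$e, rig$tr, default_profile, sample_size = 1)
  id_row <- Filter(function(r) r$path == id_path, rep2$rows)[[1]]
  expect_identical(id_row$samples, first_vals[1])
})

test_that("a clean compliant source yields zero issues", {
  rig <- rig_for(clean_spec())
  rep <- build_mapping_report(rig$e, rig$tr, default_profile)
  expect_length(rep$issues, 0L)
})

test_that("a concept under a drop rule shows dropped > 0 in its row", {
  rig <- rig_for(clean_spec(drop_rules = list(
    drop_rule(name_path, "outside_value_list", values = "Fagus sylvatica"))))
  rep <- build_mapping_report(rig$e, rig$tr, default_profile)
  name_row <- Filter(function(r) r$path == name_path, rep$rows)[[1]]
  expect_gt(name_row$stats$dropped, 0L)
  expect_identical(name_row$stats$dropped, sum(rig$p$drop_ledger$count))
})

test_that("compliance: a profile with no mandatory rules never errors", {
  caps <- capabilities_report(list())
  prof <- target_profile("lax", list(
    list(target_concept = "dc:x", source_paths = "/a", mandatory = FALSE,
         unique = FALSE)))
  issues <- check_compliance(caps, list(), prof)
  expect_length(issues, 1L)
  expect_identical(issues[[1]]$code, "unmapped_target")
  expect_identical(issues[[1]]$severity, "warning")
})

test_that("each injected defect yields exactly its one expected issue", {
  # missing mandatory: unmap the multimedia concept
  spec <- clean_spec()
  spec$concepts <- Filter(function(cc) cc$path != uri_path, spec$concepts)
  rig <- rig_for(spec)
  rep <- build_mapping_report(rig$e, rig$tr, default_profile)
  expect_identical(vapply(rep$issues, `[[`, character(1), "code"),
                   "missing_mandatory")
  expect_identical(rep$issues[[1]]$target_concept, "europeana:object")
  expect_identical(rep$issues[[1]]$severity, "error")

  # duplicate unique: two records share a unit id
  rig2 <- rig_for(clean_spec())
  rig2$p$delivered[[2]]$values[[id_path]] <-
    rig2$p$delivered[[1]]$values[[id_path]]
  rig2$p$table <- rig2$p$delivered
  rep2 <- build_mapping_report(rig2$e, rig2$tr, default_profile)
  expect_identical(vapply(rep2$issues, `[[`, character(1), "code"),
                   "duplicate_unique")
  expect_identical(rep2$issues[[1]]$path, id_path)

  # dataset repetition
  rig3 <- rig_for(clean_spec(repeat_ds = TRUE))
  rep3 <- build_mapping_report(rig3$e, rig3$tr, default_profile)
  expect_identical(vapply(rep3$issues, `[[`, character(1), "code"),
                   "dataset_repetition")
  expect_identical(rep3$issues[[1]]$severity, "warning")

  # unmapped optional target: drop the locality concept
  spec4 <- clean_spec()
  spec4$concepts <- Filter(function(cc)
    cc$path != "/DataSets/DataSet/Units/Unit/Gathering/LocalityText",
    spec4$concepts)
  rig4 <- rig_for(spec4)
  rep4 <- build_mapping_report(rig4$e, rig4$tr, default_profile)
  expect_identical(vapply(rep4$issues, `[[`, character(1), "code"),
                   "unmapped_target")
})

test_that("a mapped but unsearchable concept draws a not_searchable
           warning", {
  spec <- clean_spec()
  spec$concepts <- lapply(spec$concepts, function(cc) {
    if (cc$path == uri_path) cc$searchable <- FALSE
    cc
  })
  rig <- rig_for(spec)
  rep <- build_mapping_report(rig$e, rig$tr, default_profile)
  codes <- vapply(rep$issues, `[[`, character(1), "code")
  expect_identical(codes, "not_searchable")
  expect_identical(rep$issues[[1]]$severity, "warning")
})

test_that("dataset repetition is flagged only when blocks equal units and
           more than one unit was served", {
  mk <- function(n_units, n_blocks) {
    recs <- lapply(seq_len(n_units), function(i)
      unit_record(paste0("u", i), list("/p" = "x")))
    biocasemon:::new_response("search", record_count = n_units,
                              records = recs,
                              dataset_meta = list("/m" = "T"),
                              n_dataset_blocks = n_blocks)
  }
  expect_identical(check_dataset_repetition(mk(7, 7))$code,
                   "dataset_repetition")
  expect_null(check_dataset_repetition(mk(7, 1)))
  expect_null(check_dataset_repetition(mk(1, 1)))
})

test_that("profile switching changes exactly the issues of the rules that
           differ", {
  rig <- rig_for(clean_spec())
  pal_profile <- load_profile(file = extdata("profiles", "paleontology.tsv"),
                              name = "paleontology")
  rep_def <- build_mapping_report(rig$e, rig$tr, default_profile)
  rep_pal <- build_mapping_report(rig$e, rig$tr, pal_profile)
  def_codes <- vapply(rep_def$issues, function(i)
    paste(i$code, i$target_concept %||% "", sep = ":"), character(1))
  pal_codes <- vapply(rep_pal$issues, function(i)
    paste(i$code, i$target_concept %||% "", sep = ":"), character(1))
  # the paleontology profile adds a mandatory chronostratigraphic term this
  # zoological source does not map; every shared rule judges identically
  expect_setequal(setdiff(pal_codes, def_codes),
                  "missing_mandatory:dcterms:temporal")
  expect_length(setdiff(def_codes, pal_codes), 0L)
})

test_that("clean random providers audited under a matching profile raise
           no issues", {
  with_seed(501, {
    for (i in 1:20) {
      paths <- paste0("/s/", replicate(sample(2:4, 1),
        paste(sample(letters, 6, replace = TRUE), collapse = "")))
      paths <- unique(paths)
      concepts <- lapply(paths, function(p)
        spec_concept(p, value_pool = sprintf("%s-%03d", substr(p, 4, 9), 1:300),
                     distinct_values = p == paths[1]))
      spec <- provider_spec(concepts, n_records = sample(3:40, 1),
                            seed = sample.int(1e6, 1))
      prof <- target_profile("gen", lapply(seq_along(paths), function(j)
        list(target_concept = paste0("t", j), source_paths = paths[j],
             mandatory = TRUE, unique = j == 1L)))
      rig <- rig_for(spec)
      rep <- build_mapping_report(rig$e, rig$tr, prof)
      expect_length(rep$issues, 0L)
    }
  })
})

test_that("HTML is the default rendering and lists issues in a message
           box; XML parses back with every row and issue", {
  rig <- rig_for(clean_spec(repeat_ds = TRUE))
  rep <- build_mapping_report(rig$e, rig$tr, default_profile)
  expect_identical(render_mapping_report(rep),
                   render_mapping_report(rep, "html"))
  html <- render_mapping_report(rep)
  expect_match(html, '<section class="message-box">', fixed = TRUE)
  expect_match(html, "dataset_repetition", fixed = TRUE)
  xml <- render_mapping_report(rep, "xml")
  back <- parse_mapping_report_xml(xml)
  expect_length(back$rows, length(rep$rows))
  expect_length(back$issues, length(rep$issues))
  expect_identical(back$profile, "default")
  expect_identical(vapply(back$rows, function(r) r$stats$total, integer(1)),
                   vapply(rep$rows, function(r) r$stats$total, integer(1)))
  expect_error(render_mapping_report(rep, "pdf"))
})

test_that("scan views list every unique value as XML, escaping special
           characters losslessly", {
  p <- make_provider(provider_spec(
    list(spec_concept("/p", value_pool = c("a&b<c>", "café", "\"quoted\"",
                                           "plain"))),
    n_records = 30, seed = 8))
  tr <- mock_transport(list("mock://x" = p))
  doc <- scan_view(endpoint("mock://x"), tr, "/p")
  vals <- xml2::xml_text(xml2::xml_find_all(xml2::read_xml(doc), "//value"))
  expect_identical(vals, scan_concept(endpoint("mock://x"), tr, "/p"))
  bad <- scan_view(endpoint("mock://x"), tr, "/unmapped")
  expect_match(bad, 'level="error"', fixed = TRUE)
})

test_that("a valueless mapped concept yields an empty but valid scan view", {
  p <- make_provider(provider_spec(
    list(spec_concept("/p", value_pool = "x"),
         spec_concept("/q", value_pool = "y", presence = 0.99)),
    n_records = 5, seed = 2,
    drop_rules = list(drop_rule("/q", "missing_mandatory", pattern = "*"))))
  tr <- mock_transport(list("mock://x" = p))
  doc <- scan_view(endpoint("mock://x"), tr, "/q")
  expect_length(xml2::xml_find_all(xml2::read_xml(doc), "//value"), 0L)
})
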