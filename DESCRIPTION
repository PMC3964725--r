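Package: biocasemon
Title: Monitoring and Mapping Audits for BioCASe-Style Collection-Data Networks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable toolkit for quality assurance of distributed
    biodiversity collection-data networks that publish ABCD-style records
    through an XML-over-HTTP query protocol. Implements the protocol dialect
    (capabilities, search and scan requests with a filter algebra), a client
    that derives per-concept total/distinct/dropped value statistics, a
    timestamped file cache with interval expiry, a multi-source monitor with
    TSV/HTML/JSON export, and a mapping checker that validates a source's
    schema mapping against switchable target-schema requirement profiles
    (mandatory and unique constraints, dataset-repetition warning). Ships a
    deterministic synthetic provider that doubles as the counting oracle, so
    the whole toolkit is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    digest,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
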