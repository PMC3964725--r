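# biocasemon

Quality-assurance toolkit for distributed biodiversity collection-data
networks. Coordinators of such networks federate many institutional
databases, each wrapped by provider middleware that maps local fields onto
a hierarchical exchange schema (ABCD-style concepts addressed by
x-path-like element paths) and answers an XML-over-HTTP query protocol
with three request kinds: *capabilities* (mapped concepts with a
`searchable` flag and data type), *search* (records or record counts,
filterable and pageable) and *scan* (distinct values of one concept).

`biocasemon` turns the two recurring QA tasks into scriptable R
functions:

* **Monitoring** — one overview row per registered source with its record
  count *n*, last-modification date, baseline delta
  *Δ = n − n_baseline*, and per-concept counting columns; grouped by
  provider group; exported as TSV, HTML or JSON. Results are cached in
  timestamped plain-text files (default freshness window: 7 days).
* **Mapping auditing** — for one source, the full concept inventory with
  sample values and the per-concept triple (*total*, *distinct*,
  *dropped*), where *total* counts delivered value occurrences,
  *distinct* the unique values (so a unique identifier must satisfy
  *distinct = total*, and a multimedia `FileURI` shared by two records
  gives *distinct = total − 1*), and *dropped* the values the provider
  removed before serving (missing mandatory value, missing parent
  element, invalid encoding, or value outside the permitted list).
  Compliance is validated against switchable target-schema requirement
  profiles with mandatory/unique constraints.

Everything runs offline: the package ships a deterministic synthetic
provider (`make_provider()`) that serves the protocol from an in-memory
record table and doubles as the brute-force counting oracle
(`oracle_stats()`) every statistic is tested against.

## Worked example

```r
library(biocasemon)

spec <- read_provider_spec(system.file("extdata/provider-herbar.json",
                                       package = "biocasemon"))
provider <- make_provider(spec)
transport <- mock_transport(list("mock://herbar" = provider))
src <- endpoint("mock://herbar")

count_records(src, transport)
#> [1] 12

uri <- "/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI"
concept_stats(src, transport, uri)
#> <concept stats> /DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI: total 13, distinct 3, dropped 0
```

The synthetic herbarium serves 12 records carrying 13 multimedia URI
occurrences, only 3 of them distinct — the same media files are linked
from several specimens, which is exactly the situation the total-vs-
distinct comparison exists to reveal. Auditing the mapping against the
default (zoology/botany) requirement profile:

```r
profile <- load_profile(file = system.file("extdata/profiles/default.tsv",
                                           package = "biocasemon"),
                        name = "default")
build_mapping_report(src, transport, profile)
#> <mapping report> mock://herbar (profile 'default'): 4 concept(s), 2 issue(s)
#>   [warning] not_searchable: concept /DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI (target 'europeana:object') is mapped from literal text and cannot be filtered
#>   [warning] unmapped_target: target concept 'dc:source' is not mapped
```

All mandatory target concepts are mapped and the unit identifier is
duplicate-free, but the multimedia concept is mapped from literal text
(not filterable) and one optional target concept is unmapped — both
worth a look before harvesting. `render_mapping_report()` renders this
as HTML (default) or XML. The multi-source overview, driven by an INI
configuration:

```r
cfg <- load_config(file = system.file("extdata/monitor.ini",
                                      package = "biocasemon"))
build_overview(cfg, transport2, now = as.POSIXct("2026-03-01 12:00:00", tz = "UTC"))
#> <overview> generated 2026-03-01T12:00:00, cache interval 7 day(s)
#> [Herbaria]
#>   herbar                   12 records (+2 vs baseline)
#>   algae                     4 records
#> [Paleontology]
#>   palfish                   8 records
```

(`transport2` maps both configured mock URLs to providers; `algae` is a
logical fragment of the same physical source, restricted by a filter in
the configuration.) `export_tsv()` writes the report-ready tab-delimited
table.

A thin command-line wrapper is installed as `exec/bms`
(`bms monitor --config ... | check | scan | cache | mock`); see
`?cli`.

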