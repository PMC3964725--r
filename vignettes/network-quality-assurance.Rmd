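---
title: "Monitoring and auditing distributed collection-data networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring and auditing distributed collection-data networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocasemon)
```

## The problem

Biodiversity data networks federate hundreds of institutional databases.
Each institution wraps its collection database with provider middleware
that maps local fields onto a hierarchical exchange schema (ABCD-style
concepts addressed by x-path-like element paths) and answers an
XML-over-HTTP query protocol. Network coordinators are responsible for
data quality across all of these sources, which raises two recurring
questions:

1. **Progress monitoring** — how many records does each source serve, how
   do counts of key concepts (taxon names, localities, multimedia
   objects) develop, and how does today's figure compare to a funding
   baseline?
2. **Mapping auditing** — is a single source's schema mapping complete,
   searchable where it needs to be, and ready for transformation into a
   consuming target schema (e.g. an aggregator's format) whose concepts
   carry mandatory and uniqueness constraints?

`biocasemon` implements both as a scriptable toolkit. Everything runs
offline against a deterministic synthetic provider that doubles as a
brute-force counting oracle, so the whole chain — protocol, client,
cache, monitor, checker — is testable without touching production
endpoints.

## The protocol dialect

Sources are queried through three request kinds: *capabilities* (which
concepts are mapped, whether each is *searchable*, and its declared data
type), *search* (unit records or a bare record count, filterable and
pageable) and *scan* (the distinct values of one concept). The filter
algebra has six comparisons (`equals`, `like`, `lessThan`,
`lessThanOrEquals`, `greaterThan`, `greaterThanOrEquals`), null checks
(`isNull`, `isNotNull`), negation and `and`/`or` junctions. Every request
declares protocol version 1.3.

The original service never publishes its wire schema, so this package
defines and documents its own dialect with the same request kinds and
operators (see `?protocol`). Compatibility with production endpoints is
therefore best-effort; the dialect itself is frozen by round-trip
property tests and deterministic serialization (equal envelopes produce
byte-identical documents).

Semantics decided here, where the field leaves room:

* A comparison is **existential** over a multi-valued concept: it is true
  if any value at the path satisfies it, and false on an absent path.
* `isNull` means *path absent*; an empty string is a present value. This
  distinguishes "unmapped/empty for this record" from "mapped but blank",
  which matters when filters partition a physical source into logical
  fragments (`count(f) + count(not f)` always equals the unfiltered
  count, because evaluation is total).
* Ordering comparisons are numeric when **both** operands parse as
  decimal numbers, else lexicographic on Unicode code points (locale
  independent, so results are stable across machines).
* `like` supports `*` as its only wildcard; `equals` is case-sensitive.
* Scan results are returned sorted in code-point order. Whether real
  servers sort their scan output is unknown; sorting here makes every
  downstream artifact deterministic.

## Counting semantics: total, distinct, dropped

For any concept, the toolkit reports three numbers:

* **total** — the number of delivered value *occurrences* across matching
  records. Occurrences, not records: a specimen record linking three
  multimedia files contributes three. This is what makes the
  total-vs-distinct comparison informative for concepts like `FileURI`,
  where one media object shared by two records gives `distinct = total - 1`.
* **distinct** — the number of unique delivered values (the scan result
  length). `distinct < total` on a unique-constrained concept (e.g. a
  unit identifier) signals erroneous duplication.
* **dropped** — values present in the source database but absent from the
  XML response. Provider middleware drops a value when a mandatory value
  is missing, when a parent element at a higher hierarchy level is
  missing, when the value is invalid (e.g. wrong character encoding), or
  when it falls outside the schema's permitted value list.

How the original service learns the dropped count is not published; this
package has the provider report drops through *drop-report diagnostics*
(code `droppedValue`, carrying concept and count) attached to each served
page, and the client accumulates them during retrieval. That is one
admissible reading; it keeps the client free of any database-side
knowledge.

## The synthetic provider

`provider_spec()` + `make_provider()` build an in-memory source:
per-concept value pools, single or multi-valued (1–3 values) concepts, a
presence probability for optionally mapped concepts, dataset-level
metadata, and rule-driven value dropping with the four reasons above. The
generator is seeded and keeps no global RNG state: equal (spec, seed)
yields byte-identical tables, and the session RNG is untouched.

Generator choices that define the test conditions:

* Random audit providers use up to 200 records and up to 8 concepts —
  small enough for the brute-force oracle to be obviously correct, large
  enough to exercise paging, multi-valued concepts and drop rules.
* Identifier-like concepts can be drawn without replacement
  (`distinct_values = TRUE`), since real inventory numbers are unique;
  duplicated identifiers are then an *injected defect*, not generator
  noise.
* Dropping is modeled at value-occurrence granularity, matching the
  per-concept dropped column. When a rule empties a parent concept's
  values in a record, occurrences of hierarchically dependent child
  concepts are dropped too and ledgered under `parent_missing`.
* `repeat_dataset_per_unit` reproduces the normalization defect where
  dataset metadata is emitted once per unit.

What the mock does **not** emulate: real SQL wrapping, encoding
corruption in transit, schema-version drift, slow or flaky networks
(outages are injected as clean transport failures), and the size of
production sources (10^6-record sources are out of scope for the test
envelope). Passing tests therefore demonstrate the correctness of the
counting, caching and compliance logic, not wire compatibility with any
production installation.

## Client, cache and monitor

The client (`count_records()`, `scan_concept()`, `fetch_all_records()`,
`concept_stats()`) talks through an injectable transport, defaulting to
30 s timeout, 2 retries and a page size of 100. Paging is lossless and
duplication-free for any page size; every statistic equals the oracle
exactly, which is the package's central acceptance property.

Results are cached in plain text files — first line an ISO-8601
timestamp, rest the payload — keyed by a digest of (url, operation,
concept, serialized filter), so logical fragments of one physical source
cache independently. An entry is fresh for `cache_interval_days`
(default 7, configurable); `renew` force-invalidates a source. The clock
is always passed in, never read inside the cache, so expiry is exactly
testable. An unreachable verdict is cached separately with a 1-hour TTL:
a down provider does not stall every rebuild, but its long-lived entries
are never poisoned. A warm cache serves a full rebuild with zero
transport calls.

`build_overview()` assembles one row per configured source (INI
configuration, `?registry` documents the grammar) in declared group and
source order; a failing source yields an `unreachable` row rather than
aborting. Output formats: TSV (the reporting export; columns `group`,
`name`, `endpoint`, `status`, `records`, `last_modified`, `delta`,
`links`, then a total/distinct pair per configured concept), HTML (one
static section per provider group — the interactive collapsing of the
original web page is left to the consuming page) and JSON (round-trips
to an equal overview). The `delta` column is current minus baseline
count, the progress indicator used when a funding period fixes a
reference count.

## The mapping checker

`build_mapping_report()` audits one source: one row per mapped concept
with searchability, data type, sample values (default 5, taken from the
first records served — "first records" is unquantified in the original
service, 5 is this package's choice), the total/distinct/dropped triple,
and the resolved target concept under the active requirement profile.
Profiles are tab-delimited files (`target_concept`, `;`-separated
alternative `source_paths`, strict `0/1` `mandatory` and `unique`
flags); three fixture profiles ship with the package mirroring a default
(zoology/botany), a mineralogy and a paleontology setting, and profiles
are switchable per run.

Compliance rules, in profile order:

* mandatory target with no mapped alternative → **error**
  `missing_mandatory`;
* unique-constrained target whose mapped path delivers
  `distinct < total` → **error** `duplicate_unique` (uniqueness is judged
  on delivered values — detectable without target-side knowledge);
* mapped but unsearchable path → **warning** `not_searchable`
  (searchability is important to check but not forbidden to lack);
* unmapped optional target → **warning** `unmapped_target`.

`check_dataset_repetition()` warns when the dataset metadata block count
equals the unit count with more than one unit served. A one-unit source
is ambiguous and deliberately not flagged.

Reports render as HTML by default; XML output is supported for further
machine processing and parses back completely
(`parse_mapping_report_xml()`). The checker also works stand-alone: a
service URL carrying the access point in its `url` query parameter is
accepted anywhere an endpoint is (`parse_checker_url()` takes the
parameter value verbatim to the end of the string, preserving the access
point's own embedded query string, and percent-decodes exactly once).

## Numerical and design notes

* All sorting uses radix (C-locale) order; ties in report ordering follow
  configuration or profile order, never hash order.
* Concurrency is a contract, not an implementation: sources may be
  fetched in any order, results are merged in configuration order, and
  outputs are byte-stable given a pinned clock.
* The command line (`exec/bms`, `bms_main()`) exposes monitor / check /
  scan / cache subcommands plus `mock`, which serves a single protocol
  request from a provider-spec JSON in batch mode — the offline stand-in
  for running a provider as a server. Exit codes: 0 success, 1 usage
  error, 2 endpoint or compliance error.
* Test problem sizes — 100 random providers of up to 200 records for the
  oracle-equivalence sweep, 500 filter/record pairs for the algebra laws —
  were chosen as the smallest sets that exercise every code path several
  times over while keeping the whole suite comfortably interactive.

## Known limitations

* The dialect is this package's own; no claim of wire compatibility with
  production BioCASe installations is made or tested.
* Dropped-value counts rely on the provider reporting drops; a provider
  that silently omits values is indistinguishable from one with nothing
  to drop.
* `http_transport()` is a minimal GET carrier for live experimentation
  and is not exercised by the test suite.
* The cache trusts file mtimes not at all (timestamps live in the files),
  but it does assume a POSIX rename is atomic on the cache directory's
  filesystem.
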