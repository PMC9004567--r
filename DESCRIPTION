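Package: gerotarget
Title: Cross-Disease Aggregation and Prioritization of Aging-Related Drug Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-purpose (aging plus disease) drug-target discovery
    from ranked per-disease target lists and case-control log-fold-change
    tables. Aggregates top-ranked genes across age-associated and
    non-age-associated diseases by occurrence and mean rank, classifies
    targets as disease-category specific or common, filters candidates by
    unidirectional expression consistency across disease classes, annotates
    targets with hallmarks of aging, and tests overlap with curated
    aging-gene pools by a hypergeometric enrichment statistic over a
    druggable-gene background. Includes a seeded synthetic-data generator
    with planted ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
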