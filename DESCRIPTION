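Package: termaudit
Title: Integration and Consistency Auditing of Two-Level Adverse-Event Terminologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges many two-level (category term / preferred term) adverse-event
    terminology sets, such as the 89 JFMDA medical-device terminologies, into one
    labeled graph per problem domain using a fixed relation schema (subClassOf,
    hasSynonym, correspondenceOf, isDefinedBy), then runs six structural
    consistency checks plus hierarchy-cycle detection and emits quantitative
    audit reports. Includes deterministic Turtle/N-Triples export, a synthetic
    terminology generator with planted, countable inconsistencies, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    igraph,
    jsonlite,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
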