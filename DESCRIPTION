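Package: tcscensus
Title: Census and Classification of Archaeal Two-Component Signal
    Transduction Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for the census of two-component signal transduction
    (TCS) systems in archaeal genomes. Classifies proteins into histidine
    kinase and response regulator classes from domain-hit evidence, resolves
    overlapping domain hits into linear architectures, delineates candidate
    novel output domains from unassigned regions, scores conservation of the
    receiver (REC) domain active site against a CheY reference, analyses gene
    neighborhoods, chemotaxis operons and membrane localization, and
    aggregates per-genome and per-taxon census tables. Includes a synthetic
    genome generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
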