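Package: genolims
Title: Laboratory Information Management for Sanger Sequencing and
    Microsatellite Genotyping Labs
Version: 0.1.0
Authors@R:
    person("genolims", "developers", email = "dev@genolims.example.org",
           role = c("aut", "cre"))
Description: A headless laboratory information management system (LIMS) for
    small-to-medium molecular genetics labs running Sanger sequencing and
    microsatellite genotyping projects. Provides a 23-relation embedded
    SQLite data model guarded by a declarative business-rule layer, a
    controlled-vocabulary code system, a five-level hierarchical storage
    tree with sample placement and full location paths, individual and
    sample registries with arbitrary external identifier systems, workflow
    capture (collection, DNA extraction, PCR, validation, electrophoresis,
    raw-file blobs), import of final sequence and microsatellite data,
    atomic batch migration of historical data from spreadsheets with
    foreign-key resolution and similar-key detection, export of sequences
    to seven alignment formats and genotype matrices in three layouts,
    thirteen predefined reports, dual-matrix role-based access control, a
    command-line interface, and a deterministic demo-data generator.
License: GPL (>= 2)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    Biostrings,
    digest,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
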