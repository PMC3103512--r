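Package: crmpred
Title: Prediction and Prioritization of Conserved Cis-Regulatory Modules in Teleost Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide prediction of cis-regulatory modules (CRMs) from
    clusters of conserved transcription-factor binding sites. Scans
    soft-masked genome sequence with position-weight matrices under a
    uniform background model, combines reference-genome hits with support
    from orthologous regions in comparison teleost genomes using a
    misalignment-tolerant conservation score, clusters conserved hits into
    scored CRMs, selects pan-vertebrate conserved candidates by local
    alignment to the human orthologous neighborhood, and provides the
    downstream statistics: genomic-location bias against a size-matched
    randomization null, ortholog-transferred tissue-enrichment testing with
    false-discovery-rate control, and the bookkeeping for an
    injection-based enhancer assay. Ships a deterministic synthetic-fixture
    generator so the complete pipeline can be exercised end to end on toy
    multi-species data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
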