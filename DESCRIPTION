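Package: moanet
Title: AOP-Based Mechanism-of-Action Networks from Exposure Transcriptomics
Version: 0.1.0
Authors@R:
    person("FHAIVE", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Converts exposure transcriptomics into mechanism-of-action (MOA)
    networks grounded in the adverse outcome pathway (AOP) framework.
    Provides per-exposure co-expression network inference via a pairwise
    Hotelling T-squared test, topological enrichment of AOP key events by
    shortest-path statistics against size-matched random gene sets,
    prioritization of molecular initiating events and adverse outcomes,
    network information scores (completeness, key-event connectivity),
    a biological-system similarity score, cohort-level network comparison
    (edge-similarity consensus clustering, overrepresented-edge extraction,
    edge-set enrichment), a simplified benchmark-dose gene filter, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    cluster,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
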