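Package: phenokit
Title: Integration and Analysis of Heterogeneous Plant Phenology Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing plant phenology observations collected under
    status-based monitoring (repeated per-visit yes/no records with optional
    intensity ranges, as used by networks such as USA-NPN and NEON) and
    event-based monitoring (first-date records with BBCH-like codes, as used by
    PEP725). Provides a trait catalog of plant structures and phenological
    traits with machine-derived present/absent convenience-class hierarchies, an
    inference engine that classifies count and percentage measurement ranges
    into presence/absence classes and materializes their full subsumption
    closure, a four-stage ingestion pipeline producing a flat queryable table,
    onset analyses (0.1-degree gridding, earliest observation per grid cell and
    year, decade filtering, per-decade medians, Gaussian kernel density
    estimates with the interquartile-range rule-of-thumb bandwidth), and a
    seeded simulator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
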