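Package: litminer
Title: Literature-Mined, Tissue-Contextual Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A semi-automated workflow for building and analysing a
    bait-protein-centric, tissue-contextual protein-protein interaction
    network from literature-mining evidence. Covers PRISMA-style corpus
    screening, dictionary-based gene/protein name recognition and
    bait-partner sentence co-mention extraction, a typed bait-centric
    network model with five interaction subnetworks and GPML pathway I/O,
    comparison against reference interaction databases with
    tissue-expression filtering, and exact-test overrepresentation
    analysis of differential-expression results within subnetworks.
    Seeded synthetic-data generators with attached ground truth make
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    stringr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
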