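Package: ppimod
Title: Phenotype Module Discovery in Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Guilt-by-association candidate prioritization and module
    analysis for scored protein-protein interaction (PPI) networks.
    Reads STRING-style combined-score edge lists, filters and
    deduplicates them, scores every non-seed protein with the Hishigaki
    neighborhood chi-square statistic against a seed set, extracts the
    induced phenotype module for the top-ranked candidates, detects
    dense sub-modules with a reimplementation of the MCODE algorithm,
    calls intramodular (top-decile degree) and intermodular
    (multi-sub-module spanning) hub proteins, and tests annotation terms
    for over-representation with the hypergeometric distribution.
    Includes a synthetic STRING-like network generator with planted,
    seed-enriched communities so the whole pipeline can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
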