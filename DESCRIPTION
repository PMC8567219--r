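Package: phosphoflow
Title: SILAC Phosphoproteomics Ratio Normalization, Site Assembly and
    Proximity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative SILAC phosphoproteomics of
    evidence-style peptide tables: ratio orientation and mixing normalization
    with arginine-to-proline conversion correction, phosphosite localization
    filtering and aggregation into phosphorylation sites, phosphoislands and
    unphosphorylated counter groups, integration of multiple experimental
    setups with fold-change classification and enrichment testing, iterative
    motif-x style sequence-motif extraction, and densitometry-based M-Track
    proximity statistics with dilution-curve loading correction. Includes a
    synthetic-data generator with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
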