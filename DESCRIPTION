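Package: ampenrich
Title: Structure-Function Enrichment Analysis for Antimicrobial Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidirectional enrichment analysis between structural categories
    and antimicrobial activities of peptides. Builds sequence-identity
    representative sets by greedy clustering, assigns fold clusters from
    C-alpha traces via TM-score superposition at the 0.5 topology cutoff,
    tests both enrichment directions with a log-space hypergeometric tail
    and Benjamini-Hochberg correction, classifies mutual enrichments as an
    arrow matrix across identity thresholds, and summarises conserved
    sequence motifs of enriched peptide sets. Includes a synthetic data
    generator with planted structure-function associations for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
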