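Package: txpcover
Title: Epitope Selection for Immunoaffinity Mass Spectrometry by Set Cover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs minimal panels of short terminal epitopes (TXP antigens)
    for immunoaffinity enrichment of tryptic peptides before mass
    spectrometry. Performs a complete in-silico tryptic digest of a proteome,
    enumerates peptide/terminal-epitope combinations, filters them for
    mass-spectrometric detectability (unknown residues, methionine-bearing
    epitopes, overloaded epitopes, near-isobaric peptides, detector length
    range, high-abundant-protein stop lists), builds the bipartite
    protein-epitope cover graph, and selects epitope sets by greedy
    heuristics or exact binary linear programming: minimum set cover,
    enforced multicover, and budgeted maximum multicover. Includes a seeded
    synthetic-proteome generator with planted structure for end-to-end
    testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
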