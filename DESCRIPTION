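Package: itsfold
Title: Secondary-Structure Constraint Analysis of Ribosomal Internal Transcribed Spacers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective constraint on the secondary structure of nuclear
    ribosomal internal transcribed spacers (ITS1/ITS2). Folds spacer sequences
    with a nearest-neighbour minimum-free-energy engine (with base-pair
    maximization and suboptimal-structure enumeration), extracts per-sequence
    structural statistics (lowest energy state, number of structures, hairpin
    and paired-nucleotide counts), compares them against length- and GC-matched
    random sequences and among taxonomic groups with rank tests, computes
    alignment descriptive statistics (variable and parsimony-informative sites,
    simple indel coding of gaps), and generates ITS-like synthetic sequence
    families with controllable structural constraint for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
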