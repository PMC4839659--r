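Package: smrnakit
Title: Small RNA Discovery and Annotation from Short-Read Libraries
Version: 0.1.0
Authors@R:
    person("Maintainer", "smrnakit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and annotating small
    regulatory RNAs in a GC-rich microalgal genome from collapsed
    short-read libraries: read collapsing and length/contaminant
    filtering, exact-match placement of reads on both genome strands,
    minimum-free-energy hairpin folding with MIRcheck-style precursor
    curation and miRNA* duplex detection, plant- and animal-style miRNA
    target prediction with GO level-2 clustering, endogenous siRNA
    classification (repeat-associated, phased trans-acting with a
    hypergeometric phasing statistic, natural-antisense, and
    piRNA-like), and stem-loop RT-qPCR quantification arithmetic.
    Includes a truth-labelled synthetic genome and read simulator so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
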