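Package: cpgphylo
Title: CpG-Based Phylo-Epigenetic Analysis of Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring species relationships from the conservation
    of CpG dinucleotides in multiple sequence alignments. Classifies CpG
    sites by evolutionary conservation, recodes preserved CpG sites into
    binary epigenetic characters, computes dinucleotide divergence
    statistics, and builds rooted UPGMA trees from both ordinary nucleotide
    p-distances (SNP mode) and CpG-recoded characters (CpG mode). Includes
    a context-dependent sequence-evolution simulator with elevated
    deamination-driven transition rates at methylated CpG sites and
    protected CpG islands, for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
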