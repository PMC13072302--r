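Package: mitocub
Title: Codon Usage Bias Analysis for Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for quantifying codon usage bias in annotated
    mitochondrial genomes and attributing it to mutation pressure versus
    natural selection. Reads GenBank flat files or feature tables, extracts
    strand-correct coding sequences, and computes gene arithmetic (lengths,
    overlaps, start/stop codon census), nucleotide composition and skews,
    relative synonymous codon usage (RSCU) with over/under-representation
    calls, Wright's effective number of codons with the expected-ENC curve
    and ENC-ratio classification, parity rule 2 (PR2) coordinates, the
    GC12-on-GC3 neutrality regression with its decision rules, Nei-Gojobori
    Ka/Ks under the vertebrate mitochondrial code, and group-average (UPGMA)
    clustering of species RSCU profiles. A seeded synthetic-data module
    generates toy mitogenomes, neutrality-regime codon sets, and
    omega-controlled divergent coding sequences for testing and simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
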