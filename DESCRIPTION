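Package: sscpkit
Title: Design and Analysis Toolkit for PCR-SSCP Fingerprint Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for single-strand conformation polymorphism (SSCP)
    screening workflows built around small-subunit rDNA markers. Computes
    per-column Shannon entropy and similarity conservation profiles over a
    nucleotide multiple sequence alignment, searches conserved windows for
    universal primer pairs and screens candidates with nearest-neighbor
    duplex thermodynamics (melting temperature, self-dimer, hairpin and
    heterodimer free energies), performs in-silico PCR with mismatch and
    3'-anchor rules followed by size filtering and exact-identity amplicon
    grouping, and analyses digitized gel fingerprints: ladder-based
    migration-curve normalization across gels, tolerance-matched band
    similarity, UPGMA dendrograms and partition-congruence statistics.
    Deterministic simulators for alignments, template sets and multi-gel
    band tables support fully reproducible desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    ape,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
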