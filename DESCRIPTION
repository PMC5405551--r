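Package: mitohet
Title: Low-Frequency Heteroplasmy Calling on Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mitochondrial DNA heteroplasmy from deep paired-end
    sequencing of circular genomes. Builds strand-resolved, quality-filtered
    pileups from SAM alignments against both the original and an
    origin-shifted copy of the reference, calls low-frequency SNVs and small
    indels with a Fisher exact significance test, merges the two orientations
    by best per-position coverage, flags positions by relative coverage,
    emits a per-position CSV report and an N-masked consensus, classifies
    variants by heteroplasmy level, and screens pedigrees for parental
    transmission. Includes a seeded two-haplotype mixture read simulator for
    end-to-end benchmarking of accuracy and sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
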