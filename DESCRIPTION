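Package: panelsnp
Title: Design and Evaluation of Target-Capture Genotyping Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and evaluating liquid-phase hybridization
    capture genotyping panels (genotyping by target sequencing, GBTS) from a
    reference genome and population variant calls. Implements core polymorphic
    site selection (depth, minor allele frequency, missingness, heterozygosity,
    linkage disequilibrium pruning, microsatellite and ambiguous-base screens,
    strand-ambiguity classification), evenly spaced panel construction with
    gap detection and greedy gap filling, 110 bp GC-constrained probe window
    design with genome-wide single-copy verification, capture efficiency and
    detection-rate quality control, phenotype-stratified allele-presence
    tables, VanRaden kinship summaries, a simplified allelic chi-square
    association scan with Bonferroni thresholding, QTL grouping and candidate
    gene windows, plus a fully seeded synthetic-data generator (genome,
    population, capture counts, phenotypes) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
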