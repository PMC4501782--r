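Package: altiscan
Title: Selection Scans for Altitudinal Allele-Frequency Clines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scan for microgeographic adaptation along altitudinal
    transects. Screens SNPs for unidirectional allele-frequency clines across
    four altitude-ordered demes (the U index), lowest-vs-highest standardized
    differentiation (Hedrick's G'ST), and derived-allele-frequency increase
    relative to pooled low-altitude reference populations (delta-D'), all
    averaged in 4-kbp windows and thresholded at the Tukey upper fence of their
    genome-wide distributions. Screened SNPs are linked to nearby genes,
    hitchhiking regions ("genomic islands") are segmented from the windowed-U
    curve and ranked by area, Gene Ontology enrichment is tested SNP- and
    gene-wise with one-tailed Fisher tests and FDR q-values, and candidate-list
    overlaps between transects get Monte-Carlo empirical p-values. Includes a
    linear stepping-stone simulator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
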