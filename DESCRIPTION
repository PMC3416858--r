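Package: macrna27
Title: Small RNA Sequencing Pipeline for Ciliate Macronuclear 27 nt RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable small RNA sequencing pipeline for the analysis of the
    mating-induced 27 nt macronuclear-derived RNA class of the ciliate
    Oxytricha trifallax. Provides paired-end read collapse and adapter
    trimming, a non-coding RNA filter, construction of a concatenated
    nanochromosome reference with spacer coordinates and telomere
    annotation, an exhaustive bounded-mismatch short-read aligner with
    two-pass orchestration, length and nucleotide-composition statistics,
    Venn classification of reads against micronuclear/macronuclear gene
    pairs, strand-balance binomial envelope statistics, coverage
    coefficient of variation, and telomere-proximal density profiling.
    A synthetic-data generator emulating ciliate nuclear dimorphism
    (nanochromosomes with telomeres, IES/MDS/pointer architecture,
    bidirectional small RNA production) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
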