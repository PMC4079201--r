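Package: oligoSat
Title: Chromosome-Specific Satellite Discovery by Oligonucleotide Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes chromosome-specific satellite DNA by
    k-mer (oligonucleotide) relative-frequency profiling of a focal
    chromosome against pooled background chromosomes. Provides exact
    overlapping k-mer counting, per-position enrichment profiles,
    overrepresented-cluster calling, tandem monomer inference
    (autocorrelation period estimation and majority consensus), genome-wide
    monomer mapping by ungapped seed-and-extend search with Karlin-Altschul
    E-values, per-chromosome coverage statistics, concerted-evolution
    testing (within- versus between-locus hamming distances, Wilcoxon
    rank-sum), an exponential model of satellite density versus local
    recombination rate, and a seeded synthetic-genome simulator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
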