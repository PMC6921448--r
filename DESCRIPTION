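Package: svgt
Title: Graph-Based Genotyping of Structural Variants from Short Reads
Version: 0.1.0
Authors@R:
    person("svgt", "developers", email = "svgt@example.org", role = c("aut", "cre"))
Description: Genotypes candidate structural variants (deletions, insertions and
    blockwise sequence swaps, 50 bp and larger) in short-read samples. For each
    VCF record a local directed acyclic sequence graph is built whose paths
    spell the reference and alternative alleles; reads near the breakpoints are
    extracted from a BAM file and realigned with a junction-aware local
    Smith-Waterman; per-breakpoint haplotype read counts feed a Poisson genotype
    likelihood model with confidence filters (read count, depth, genotype
    quality, strand bias) and a breakpoint-combining decision tree. Includes
    population-level helpers (EM genotype priors under Hardy-Weinberg
    equilibrium, exact HWE filtering, SV merging and benchmark matching) and a
    paired-end read simulator so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
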