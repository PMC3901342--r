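Package: srnaforge
Title: Small RNA Sequencing Analysis for miRNA Discovery and Replicate-Free
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA-seq analysis toolkit for microRNA
    discovery and two-library comparison. Reads are adapter-trimmed,
    length-filtered and collapsed into unique tags; tags are aligned to a
    genome allowing mismatches only at the read ends; candidate precursor
    windows are folded into single stem-loop structures with a
    nearest-neighbor minimum free energy model and gated at -20 kcal/mol;
    novel miRNA genes are called, classified as conserved or
    species-specific, and annotated for isomiRs, genomic clusters, mirtrons
    and multi-copy loci. Expression is TMM-normalized and differential
    expression between two libraries without biological replicates is
    assessed with a conditional exact binomial test under a Poisson noise
    model. A synthetic-data generator with planted hairpin loci, isomiR
    spectra and fold changes makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    rlang,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
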