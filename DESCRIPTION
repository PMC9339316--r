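Package: zwscan
Title: Sex-Linked Region Detection from Coverage, FST and K-Mer Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes ZW sex-linked regions from population
    resequencing evidence. Computes windowed female/male normalized read-depth
    log2 ratios with an autosome-resampling confidence band, windowed
    intersexual Weir-Cockerham weighted FST, and sex-specific canonical k-mers
    localized on an assembly; compares phased Z and W haplotypes by
    unique-anchor chaining to call haplotype-specific insertions; annotates
    structural hallmarks of the sex-determining region (terminal inverted
    repeats, target-site duplications, LTR direct repeats, retrogene poly-A
    signatures, telomere arrays, large palindromes); and integrates the lines
    of evidence into ranked region calls. Includes a synthetic ZW genome and
    read-panel simulator with machine-readable planted truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
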