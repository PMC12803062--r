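Package: sdscan
Title: Cross-Study Scan for Male-Female Allele Frequency Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting autosomal loci whose allele frequencies differ
    between males and females consistently across several genetic studies, a
    signature of sex-differential selection or of shared participation bias.
    Provides per-SNP sex-difference chi-square tests, exact Hardy-Weinberg
    heterozygote tests with a Ramanujan large-sample log-factorial, lead-SNP
    and LD-aware gamma (MAGMA-style) gene-level aggregation, a three-study
    outlier overlap and empirical-null replication scheme, allele sign
    concordance analyses, and a forward one-generation simulator of four
    divergence mechanisms (gametic selection, viability selection,
    participation bias, and within-sex Hardy-Weinberg distortion) so the whole
    pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    pracma,
    yaml,
    jsonlite,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
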