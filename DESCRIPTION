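Package: radase
Title: Reciprocal Allele Descendant Analysis of Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies allele-specific expression (ASE) at heterozygous
    SNPs measured in genotyped parent-offspring trios into
    imprinting-dependent, genetic-variation-dependent and random
    monoallelic expression (RME) using the reciprocal allele descendant
    (RAD) pattern, the in-human analogue of a reciprocal cross.  Provides
    readers for pedigree, VCF, GTF, samtools-mpileup and allele-count
    tables, per-site chi-square allelic-imbalance calling, pairwise
    pattern grouping and site categorisation, a population-scale
    reference-versus-alternative bias test, a synthetic trio/cohort
    generator with recorded ground truth, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
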