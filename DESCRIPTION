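Package: nmisv
Title: Tagging Putative Structural Variants via Non-Mendelian Inheritance in SNP-Array Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects SNP-array loci that tag putative structural variants by
    their non-Mendelian inheritance (NMI) patterns in family trios, filters
    candidates across a discovery and a validation cohort, and quantifies
    enrichment of the candidate loci in genomic feature tracks
    (heterochromatin bands, histone marks, repeat classes, transcription
    factor binding sites, eQTLs) against a resampled null of same-size
    random SNP sets drawn from the array background. Also provides the
    binomial assay-error model for recurrent genotyping failure,
    hypergeometric gene-set term enrichment, a target-gene
    differential-expression enrichment test, and a synthetic-data generator
    with known ground truth (planted deletion alleles under array probes,
    planted track enrichment, planted excess differential expression) for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
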