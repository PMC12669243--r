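Package: rohscan
Title: Runs of Homozygosity Detection and Regional Autozygosity Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Autozygosity analysis for isolated-population cohorts: reads and
    writes PLINK binary genotypes, VCF and homozygosity-segment tables;
    applies standard cohort quality control including an exact test of
    Hardy-Weinberg equilibrium; computes LD-pruned principal components and
    the genomic relationship matrix; detects runs of homozygosity (ROH) with
    the classic sliding-window genotype scan and derives the genomic
    inbreeding coefficient F_ROH, cohort summaries and enriched ROH regions;
    correlates F_ROH with quantitative traits (Spearman, Benjamini-Hochberg);
    tests per-SNP regional autozygosity against traits under a linear mixed
    model with a GRM-structured random effect, with Bonferroni thresholding,
    LD clumping and additive and recessive genotype-model validation; and
    simulates cohorts with planted autozygous segments, genotyping noise and
    trait effects so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
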