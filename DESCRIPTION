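Package: sdscan
Title: Genome-Wide Screening for Sex-Determining Regions from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("sdscan", "developers", email = "sdscan@example.org", role = c("aut", "cre"))
Description: Maps candidate sex-determining (SD) regions from whole-genome SNP
    genotypes of sexed individuals. Computes per-locus Weir-Cockerham variance
    components with the two sexes as groups to obtain between-sex
    differentiation (FST) and the intrapopulation fixation index (FIS),
    averages both over SNP-count sliding windows, and calls candidate regions
    under dual thresholds with a minimum physical span. Candidate regions are
    classified as XX/XY or ZW/ZZ from per-sex heterozygosity, inspected for
    inversion-like recombination suppression with composite genotypic r2 and
    Monte-Carlo exact tests of genotypic disequilibrium, and re-tested in
    larger validation panels with Fisher exact tests of allelic
    differentiation. Includes a read-depth duplication check and a synthetic
    sex-linked-region simulator so the whole pipeline is verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
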