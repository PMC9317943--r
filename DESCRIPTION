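Package: qtlallele
Title: Multi-Allelic QTL-Allele Matrix Dissection and In-Silico Cross Design
    for Inbred Germplasm Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects quantitative-trait variation in panels of inbred
    accessions into a multi-allelic QTL-allele matrix and uses it to design
    crosses. Assembles haplotype-based linkage-disequilibrium block (SNPLDB)
    markers from SNP genotypes, fits a restricted two-stage multi-locus
    genome-wide association model (single-locus preselection followed by
    stepwise multi-locus selection with trait heritability as the upper bound
    on total explained variance, including QTL-by-environment terms),
    estimates variance components and heritability from multi-environment
    trials, tracks allele inheritance/emergence/exclusion between
    subpopulations, simulates homozygous progeny of all pairwise crosses under
    linkage (Poisson crossover) and independent-assortment models to rank
    crosses by progeny-value percentiles, and screens candidate genes in QTL
    intervals by chi-square independence tests. Includes a synthetic-study
    generator with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
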