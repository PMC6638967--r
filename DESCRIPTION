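Package: famlink
Title: Family-Based Linkage Mapping of Quantitative Traits in Very Large Sibships
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-trait linkage analysis for cohorts of very large
    nuclear families from founder populations. Reconstructs identity-by-descent
    (IBD) sharing and full inheritance vectors among many siblings from dense
    SNP genotypes without requiring parental genotypes, phases the four
    parental haplotypes per family, maps quantitative trait loci (QTLs) by
    permutation-calibrated haplotype contrast tests on a genome grid with a
    threshold-sweep false-discovery-rate analysis, and partitions phenotypic
    variance with genomic relatedness matrices fit jointly by EM-REML in a
    cross-validation design with a random-segment null.  A synthetic
    founder-population cohort generator (pedigrees, recombination, genotyping
    noise, and a height-like phenotype with age and sex structure) makes every
    stage testable end to end, and an analytic non-central F power calculator
    supports study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
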