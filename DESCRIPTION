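Package: altsel
Title: Genome-Wide Selection Scans and Hemoglobin Association for
    High-Altitude Population Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for detecting regionally restricted
    positive selection and testing genotype-phenotype association in
    small population samples, motivated by high-altitude adaptation
    studies.  Implements Weir-Cockerham F_ST, locus-specific branch
    length (LSBL) against two reference populations, the integrated
    haplotype score (iHS) with derived-allele-frequency-binned
    standardization, a cross-population composite likelihood ratio
    (XP-CLR style) sweep scan over genetic-map windows, empirical
    top-fraction outlier calling, gene-window pathway enrichment with
    chi-square tests, core-haplotype frequency analysis, and
    EMMAX-style linear mixed-model association of hemoglobin levels
    with age and altitude covariates.  A synthetic-data module
    generates Balding-Nichols genotypes, sweep-structured haplotypes,
    outgroup allele tables and hemoglobin phenotypes with known truth
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    vcfR,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
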