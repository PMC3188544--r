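Package: transheight
Title: Trans-Ethnic Meta-Analysis, Replication, and Fine-Mapping of Height Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of adult height in
    admixed populations: per-study additive linear regression on covariate
    adjusted Z-scores, fixed-effect inverse-variance meta-analysis with
    two-stage genomic control and heterogeneity statistics, haplotype-based
    linkage-disequilibrium computation with proxy expansion and allele
    direction prediction, an LD-aware trans-ethnic replication framework
    built on randomized SNP binning with frequency-matched permutation
    nulls, local-ancestry conditional and stratified models, and a cis-eQTL
    enrichment test.  A synthetic-data module generates two-population
    phased haplotype panels, admixed cohorts with known local-ancestry
    tracts, and height phenotypes so that the full pipeline is exercisable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
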