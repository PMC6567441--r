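Package: microherit
Title: Quantitative Genetics of Rumen Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Heritability and host-genetics analysis of microbiome features in
    livestock cohorts. From a sample-by-taxon count table, a biallelic SNP
    panel, and per-animal metadata, the package derives microbial traits
    (rank-collapsed, detection-filtered, log10-transformed relative abundances
    with outlier removal; rarefied alpha diversity; Bray-Curtis principal
    coordinates), performs SNP quality control and builds a VanRaden genomic
    relationship matrix, estimates narrow-sense heritability of each feature
    under a genomic animal model fitted by spectral-decomposition REML, runs a
    single-marker mixed-model association scan with Benjamini-Hochberg false
    discovery rates, infers compositional co-occurrence networks with the
    SparCC algorithm and permutation p-values, and screens heritable features
    against feed-efficiency and rumen-fermentation traits. A synthetic-data
    module simulates half-sib genotype panels, polygenic and QTL-affected
    traits, and compositional count tables with known ground truth so the
    whole chain is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
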