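# microherit

Quantitative genetics of rumen microbial communities: which features of a
livestock microbiome are heritable, and which host variants move them?

## The problem

Rumen microbes digest the fiber that cattle cannot, and community composition
co-varies with feed efficiency and fermentation chemistry. If part of that
variation is under host genetic control, microbial features become breedable
traits. Answering this requires stitching together two toolchains that rarely
meet: microbial ecology (count tables, rarefaction, diversity, ordination,
compositional correlation networks) and quantitative genetics (SNP QC,
genomic relationship matrices, REML variance components, mixed-model GWAS).
`microherit` implements that full chain for genotyped cohorts with 16S-style
taxon count tables, plus a synthetic-data module that simulates every input
with known ground truth so each stage is testable end to end.

## The model at the core

Each microbial feature *y* (a log10 relative abundance, an alpha-diversity
index, or a principal-coordinate score) is analyzed under the genomic animal
model

> y = Xβ + a + e,  a ~ N(0, G σₐ²),  e ~ N(0, I σₑ²)

with fixed effects of breed, sex, diet, and age in X, and G the VanRaden
genomic relationship matrix built from SNP dosages, G = ZZᵀ / (2 Σ pₖ(1−pₖ)).
Narrow-sense heritability is **h² = σₐ² / (σₐ² + σₑ²)**. The fit is REML via
one spectral decomposition of G and a 1-D profile of the restricted
likelihood over the variance ratio λ = σₐ²/σₑ² — exact for a single genetic
variance component, with SEs from the profile curvature. Features with
h² ≥ 0.1 enter a single-marker mixed-model scan (P3D: null variance
components reused per marker, genotypes coded −1/0/1, per-trait
Benjamini–Hochberg FDR; FDR < 0.1 significant, 0.1 < FDR < 0.2 suggestive).
Features with h² ≥ 0.15 are classified heritable and screened against
feed-efficiency traits (FCR = DMI/ADG; RFI = residual of DMI on ADG and
metabolic weight) and volatile fatty acid measures by Spearman correlation.
Community structure is handled with rarefied Chao1/Shannon/Simpson/Good's
coverage, Bray–Curtis PCoA, strata-aware PERMANOVA, and SparCC compositional
correlation networks with permutation p-values (edges at |r| > 0.3,
p < 0.001).

## Worked example

Simulate a 650-animal half-sib cohort (50 sires × 13 offspring, 5,000 SNPs),
give a trait a true h² of 0.25, and recover it:

```r
library(microherit)

panel  <- simulate_genotypes(pedigree_structure(50, 13), n_markers = 5000, seed = 42)
qc     <- qc_snps(panel)                      # HWE p > 1e-6, MAF >= 5%, call rate >= 90%
G      <- build_grm(impute_missing(qc$panel)) # VanRaden method 1
md     <- simulate_metadata(650, seed = 43, sample_ids = rownames(panel$dosages))
design <- build_design(md, ~ breed + sex + diet + age)

truth <- sim_truth(sigma_a2 = 0.25, sigma_e2 = 0.75)
y     <- simulate_polygenic_trait(G, design, truth, seed = 44)
fit   <- fit_animal_model(y, design, G)
summary(fit)
#> Genomic animal model (REML via spectral decomposition)
#>   n used: 650 | converged: TRUE | boundary: FALSE
#>   sigma_a2 = 0.312533
#>   sigma_e2 = 0.739457
#>   h2 = 0.2971  (SE 0.0935)
#>   restricted logLik = -941.8833
classify_heritable(fit)
#> [1] "heritable"
```

The estimate 0.297 ± 0.094 covers the true 0.25; over replicates the
estimator is unbiased with ~95% coverage of truth by ±2 SE. Now plant a QTL
explaining 5% of trait variance and scan for it:

```r
causal <- panel$map$marker[2500]
yq   <- simulate_qtl_trait(panel, G, causal, variance_fraction = 0.05, truth, seed = 45)
adj  <- adjust_phenotype(yq, design)          # OLS residuals on breed+sex+diet+age
scan <- mixed_model_scan(adj, panel, G)       # P3D mixed-model scan
head(scan[order(scan$p_value), ], 1)
#>      marker chrom     pos      beta se_beta      p_value          fdr        tier
#> 2500 rs2500    15 8455645 0.3357443  0.0638 1.967456e-07 0.0009837281 significant
```

The planted marker is the genome-wide top hit at FDR 0.001. The same engines
are chained by `run_pipeline(run_config(...))`, which takes a count table,
genotype panel, and metadata TSV and writes the heritability table,
association table, SparCC edge list, correlation screen, and a seeded run
manifest.

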