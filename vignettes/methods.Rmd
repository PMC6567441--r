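---
title: "Models and methods behind microherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistics: the models,
the tunable parameters and their defaults, what the simulators do and do not
emulate, and the numerical choices that a maintainer would otherwise have to
reverse-engineer from the code.

## The genomic animal model

Every microbial feature is analyzed as a quantitative trait of the host
animal:

$$y = X\beta + a + e, \qquad a \sim N(0,\, G\sigma_a^2), \qquad
e \sim N(0,\, I\sigma_e^2)$$

* `y` — one feature per animal: a log10-transformed relative abundance, an
  alpha-diversity index averaged over rarefaction iterations, or a
  principal-coordinate score.
* `X` — treatment-coded fixed effects: breed (3 levels), sex (bull, heifer,
  steer), diet (4 levels), and age in days as a covariate. Aliased columns
  (a diet fed to a single sex, say) are detected by QR rank inspection and
  dropped with a warning; animals missing any record are excluded, so the
  usable n varies slightly from feature to feature.
* `G` — the VanRaden (method 1) genomic relationship matrix,
  $G = ZZ^\top / (2\sum_k p_k(1-p_k))$ with dosages centered by twice the
  allele frequency observed in the post-QC data. SNP QC retains markers with
  HWE chi-square p > 1e-6, MAF ≥ 5%, and call rate ≥ 90%; remaining missing
  calls are mean-imputed (twice the allele frequency) by default, with a
  seeded draw from observed genotype frequencies as the stochastic
  alternative. Markers without a map position stay in G but are excluded
  from association scans.

Heritability is $h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)$. A feature is
called *heritable* at $h^2 \ge 0.15$ and *scan-eligible* at
$h^2 \ge 0.1$ — both inclusive, both configurable.

### REML by spectral decomposition

With a single genetic variance component, the restricted likelihood can be
profiled exactly over the variance ratio $\lambda = \sigma_a^2/\sigma_e^2$:
decompose $G = USU^\top$ once, rotate $y$ and $X$ by $U^\top$, and the
covariance becomes diagonal, $\sigma_e^2(\lambda S + I)$. The profile is
evaluated on $\lambda \in \{0\} \cup 10^{[-5,5]}$ (64 log-spaced points) and
refined by Brent search in the winning bracket; $\sigma_e^2$ then follows in
closed form. This is globally searchable and has no convergence failures, in
contrast to iterative AI-REML, at the cost of one $O(n^3)$ eigendecomposition
per feature (seconds at n = 650).

Numerical details that matter:

* Eigenvalues of G below zero (possible with finite marker panels) are
  clipped at 0; G is rejected if its smallest eigenvalue is below
  $-10^{-6}$ times the largest.
* A G proportional to the identity makes $\sigma_a^2$ and $\sigma_e^2$
  non-separable and is rejected with an explicit error.
* Optima pinned at $h^2 = 0$ or $1$ set a `boundary` flag rather than being
  silently clipped; null traits land on this boundary frequently, which is
  the expected behavior of REML at a variance of zero.
* `se_h2` is a delta-method SE from the numerical curvature (central
  differences, step $10^{-3}$) of the profile restricted likelihood in the
  $h^2$ parameterization. It approximates — and in simulation calibrates
  like — an average-information SE, but exact equality with other programs'
  SEs is not promised. Because the profile is flat near its maximum,
  re-fits of scaled data reproduce $h^2$ to about $10^{-7}$, not machine
  precision.

The rotated likelihood is verified against a dense-matrix evaluation of the
same criterion ($-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X^\top V^{-1}X| +
y^\top P y]$) to $10^{-6}$ on random instances; both routes include the same
constant so the comparison is exact, not up-to-a-constant.

### Sampling precision of h²

At the package's reference design — 650 animals in 50 paternal half-sib
families, a few thousand markers — the profile curvature puts the sampling
SD of $\hat h^2$ near 0.08–0.09 for moderate heritabilities. Two practical
consequences: single-cohort estimates must be read together with their SEs,
and the mean absolute error of recovery simulations at true $h^2 = 0.25$
settles around 0.06–0.08 (≈ 0.8 × SD for a roughly unbiased estimator) —
this is the information content of the design, not estimator slack. The
calibration claim the package does make, and tests, is that ≈95% of true
values fall inside $\hat h^2 \pm 2\,\widehat{se}$.

## Association scans

Traits are first adjusted to OLS residuals on the fixed-effect design (the
two-stage scheme), then each marker is tested by GLS under
$\sigma_a^2 G + \sigma_e^2 I$ with genotypes coded −1/0/1. The default
**P3D** mode profiles $\lambda$ once under the marker-free null and reuses
it for every marker — the standard large-cohort approximation — while
`mode = "exact"` re-profiles per marker; the two agree to rank correlation
> 0.99 in simulation. p-values use the t distribution with $n - 2$ degrees
of freedom (grand mean + marker; the choice is documented because it is not
forced by theory). Monomorphic markers are emitted with $\beta = 0$,
$p = 1$, and a flag, rather than dropped, so scan bookkeeping stays exact.
Benjamini–Hochberg FDR is applied within one trait's scan
(`stats::p.adjust`; a brute-force step-up implementation is the test
oracle), and tiers use strict inequalities: significant below 0.1,
suggestive strictly between 0.1 and 0.2 — an FDR of exactly 0.1 is neither.
With $\sigma_a^2$ forced to 0 the scan reduces, to machine precision, to
per-marker OLS — a reduction used as a correctness oracle.

## Community analyses

* **Detection filter**: a taxon is detected if its relative abundance
  exceeds 0.5% in at least one sample *and* its prevalence exceeds 20%,
  both strict; the filter is idempotent and is applied at the collapsed
  rank being analyzed, not at the OTU level.
* **Rarefaction**: samples below the target depth (2000 for bacterial,
  500 for archaeal communities by convention) are excluded outright, never
  partially subsampled; retained samples are subsampled without replacement
  per iteration (100 by default). Alpha indices — bias-corrected Chao1,
  Shannon in base 2 (matching the QIIME 1.x convention; natural log is an
  option), Simpson as $1-\sum p_i^2$, Good's coverage — are computed per
  iteration and averaged, the conventional aggregation when the source
  protocol does not state one.
* **Ordination**: classical scaling (Gower centering, eigendecomposition)
  of Bray–Curtis dissimilarities computed on a *single seeded rarefaction*;
  iteration-averaging the distance matrix is equally defensible but the
  single-rarefaction choice keeps PCoA coordinates reproducible objects of
  one subsample. Negative eigenvalues receive no Lingoes/Cailliez
  correction; explained fractions are taken over positive eigenvalues only.
* **PERMANOVA**: Anderson's pseudo-F with raw-label permutation and the
  add-one estimator $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + B)$, so p
  is never 0. `strata` constrains permutations within blocks (testing sex
  while permuting only within diet); with strata equal to the groups no
  permutation changes the labels, ties are counted as exceedances, and p is
  exactly 1. The permutation engine is implemented in the package because
  generic block-permutation utilities permute positions rather than
  labels-within-stratum, which breaks this degenerate case; the pseudo-F
  itself is cross-checked against `vegan::adonis2`.

## SparCC networks

Basis correlations are inferred from log-ratio variances
$t_{ij} = \mathrm{var}\log(x_i/x_j)$ under the sparsity assumption: basis
variances solve $[(D-2)I + J]\,\omega = $ row sums of $T$, correlations
follow as $(\omega_i + \omega_j - t_{ij}) / 2\sqrt{\omega_i\omega_j}$
(clipped to $[-1,1]$), the strongest pair above threshold 0.1 is excluded
from the system and the solve repeated (up to 10 rounds), and the whole
estimate is the elementwise median over 20 inner iterations that resample
fractions from each sample's add-one posterior Dirichlet. A deterministic
"add-one fraction" mode (one iteration, no resampling) exists for exact
tests. Defaults (20/0.1/10) are the original algorithm's. Permutation
p-values shuffle each taxon's counts independently across samples —
destroying all between-taxon association while preserving margins — and use
the same add-one estimator as PERMANOVA, so the minimum attainable p is
$1/(B+1)$. Edges require $|r| > 0.3$ and $p < 0.001$, strictly. The network
prefilter drops under-depth samples, eliminates taxa with prevalence below
20% of the remaining animals, and then subsamples once to the target depth,
in that order, so output rows sum exactly to the depth.

Two caveats the tests quantify: counting noise at finite depth attenuates
SparCC estimates for rare taxa (a planted basis correlation of 0.7 between
taxa of unexceptional abundance is recovered near 0.6–0.65 at depth 2000),
and the +1 pseudocount means per-sample total rescaling is only
approximately invariant (exactly invariant estimation would need zero-free
tables).

## Host-trait screens

FCR is DMI/ADG. RFI is the residual of a within-cohort least-squares
regression of DMI on ADG and metabolic weight (adding backfat for RFIf) — a
simplified form of the production calculation, which additionally
standardizes test periods. Log-ratio features (archaea:bacteria and the
like) are differences of log10 values. Spearman screens use average ranks
with pairwise-complete samples and t-approximation p-values (adequate at
cohort sizes in the hundreds; a seeded permutation option covers small n),
flagged at p < 0.05. Log transformation and ±3 SD outlier removal are
applied to features before screening. Outlier bounds are computed once on
the full non-missing vector, not iteratively — re-computation after removal
would tighten the bounds and was deliberately avoided. Zeros under the log10
transform default to *missing* (the model simply has fewer records); a
half-minimum pseudocount policy is available, and both are recorded in each
trait's transform log.

## The synthetic cohort

The generators exist so that every estimator above can be tested against
known truth:

* **Genotypes**: per-marker allele frequencies uniform on [0.05, 0.5] (the
  post-QC range), markers on 30 chromosomes, no linkage disequilibrium
  beyond family co-inheritance. Relatedness comes from paternal half-sib
  families — each sire's two gametes are transmitted with independent
  Mendelian sampling per marker, dams are unrelated — giving an expected
  additive relationship of 0.25 between half sibs and an eigenvalue spread
  in G sufficient for REML. The reference design, 50 sires × 13 offspring
  (n = 650), mimics a commercial multi-breed cohort whose true pedigree is
  unknown; it is a stand-in, not a reconstruction.
* **Traits**: $y = X\beta + a + e$ with $a$ drawn from
  $N(0, \sigma_a^2 G)$ via symmetric factorization (eigenvalue clipping at
  0) — the exact generative inverse of the fitted model. QTL traits scale
  one marker's effect so it explains a requested fraction of total variance
  in expectation; with fraction 0 the draw is bit-identical to the
  polygenic one.
* **Count tables**: log-normal basis abundances (per-taxon log means from
  N(0,1), log SD 1, optional planted correlation matrix, rejected if not
  positive definite) closed to fractions and sampled multinomially at fixed
  depth, the generative benchmark SparCC was designed for; a
  Dirichlet-multinomial flag adds overdispersion.
* **Metadata**: breed/sex/diet frequencies echoing a feedlot cohort, age
  ≈ 293 ± 10 days, DMI generated as a linear function of metabolic weight
  and gain plus noise so RFI has genuine signal to remove, VFA molar
  proportions from a Dirichlet centered on rumen-typical values.

What the simulators do **not** emulate: linkage disequilibrium decay,
breed-specific allele-frequency divergence, taxon-taxon interactions beyond
pairwise log-normal correlation, diet-driven compositional shifts, or
sequencing error. Passing tests therefore demonstrate that the estimators
recover truth under their own model assumptions, not that real rumen data
satisfy those assumptions.

## Problem sizes used by the test-suite

Unit tests run on cohorts of 50–200 animals and a few hundred markers; the
statistical acceptance checks use the reference design (20 cohorts of
n = 650, m = 5000 for heritability recovery; m = 2000 for scan calibration
and power; 50 taxa × 100 samples at depth 2000 for SparCC; 1000 random
vectors for FDR equivalence; an n = 200 / m = 2000 / 60-taxon cohort for
the end-to-end pipeline with 200 SparCC permutations and 199 PERMANOVA
permutations). These sizes were chosen to estimate each property with
adequate Monte-Carlo precision while keeping a full run in the minutes
range; the full-scale settings (10,000 SparCC permutations, 100
rarefaction iterations, 1000 PERMANOVA permutations) remain the package
defaults.

## Known limitations

* One genetic variance component only: no dominance, epistasis, repeated
  measures, or multi-trait REML.
* P3D and the two-stage fixed-effect adjustment are approximations; both
  are quantified against exact counterparts in the tests rather than
  hidden.
* SparCC attenuation at low counts and pseudocount non-invariance, as
  above.
* RFI is a within-cohort residual, not the full production protocol.
* The half-sib simulator cannot represent the mixture of relationships in
  a real multi-breed herd; heritability SEs from real cohorts may differ
  from the simulated calibration.
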