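# Synthetic-data generators. Every simulate_* function is a pure function of
# its arguments including the seed, so downstream stages can be tested against
# known ground truth without any animal data.

#' Ground truth record for a simulated trait
#'
#' Stores the generative values that downstream estimators are asked to
#' recover: variance components and heritability, causal markers and their
#' allele-substitution effects, planted basis correlations, fixed-effect
#' values, and the seed.
#'
#' @param sigma_a2 additive-genetic variance (trait units squared).
#' @param sigma_e2 residual variance (> 0).
#' @param causal_snp_ids,causal_betas optional causal markers and effects.
#' @param basis_correlations optional planted taxon-pair correlations.
#' @param fixed_effect_values optional named vector of fixed-effect values in
#'   design-column order.
#' @param seed RNG seed the trait was generated under.
#' @return object of class `sim_truth`; `true_h2` is
#'   `sigma_a2 / (sigma_a2 + sigma_e2)`.
#' @export
sim_truth <- function(sigma_a2, sigma_e2, causal_snp_ids = character(),
                      causal_betas = numeric(), basis_correlations = NULL,
                      fixed_effect_values = NULL, seed = NA_integer_) {
  if (sigma_a2 < 0) stop("sigma_a2 must be >= 0")
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  if (!is.null(basis_correlations) && any(abs(basis_correlations) > 1))
    stop("basis correlations must lie in [-1, 1]")
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 true_h2 = sigma_a2 / (sigma_a2 + sigma_e2),
                 causal_snp_ids = causal_snp_ids, causal_betas = causal_betas,
                 basis_correlations = basis_correlations,
                 fixed_effect_values = fixed_effect_values, seed = seed),
            class = "sim_truth")
}

#' Half-sib pedigree structure
#'
#' The simulated cohort consists of paternal half-sib families (each sire
#' mated to unrelated dams, one offspring per dam) plus unrelated animals.
#' Half-sib relatedness gives the genomic relationship matrix the
#' off-diagonal variance and eigenvalue spread that REML needs; sires and
#' dams themselves are not sampled.
#'
#' @param n_sires number of sires.
#' @param offspring_per_sire offspring per sire.
#' @param n_unrelated additional unrelated animals.
#' @export
pedigree_structure <- function(n_sires, offspring_per_sire, n_unrelated = 0) {
  total <- n_sires * offspring_per_sire + n_unrelated
  if (total <= 0) stop("pedigree structure must describe at least one animal")
  structure(list(n_sires = n_sires, offspring_per_sire = offspring_per_sire,
                 n_unrelated = n_unrelated, n_total = total),
            class = "pedigree_structure")
}

#' Simulate a biallelic SNP panel over a half-sib cohort
#'
#' Per-marker allele frequencies are drawn uniformly from `maf_range`. Each
#' sire carries two population gametes; each offspring receives one allele per
#' marker sampled from its sire's pair (independent Mendelian sampling across
#' markers, i.e. no linkage beyond family co-inheritance) plus one population
#' allele from its unrelated dam. Unrelated animals receive two population
#' alleles. Markers are laid out on `n_chromosomes` chromosomes in contiguous
#' blocks with increasing positions.
#'
#' @param structure a [pedigree_structure()].
#' @param n_markers number of markers (>= 1).
#' @param maf_range length-2 interval inside \[0.01, 0.5\].
#' @param n_chromosomes number of chromosomes to spread markers over.
#' @param seed RNG seed.
#' @return a [snp_panel()] with an attribute `families` giving each sample's
#'   sire id (`NA` for unrelated animals).
#' @export
simulate_genotypes <- function(structure, n_markers, maf_range = c(0.05, 0.5),
                               n_chromosomes = 30, seed = 1) {
  if (!inherits(structure, "pedigree_structure"))
    structure <- do.call(pedigree_structure, as.list(structure))
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval inside [0.01, 0.5]")
  set.seed(seed)
  m <- n_markers
  q <- stats::runif(m, maf_range[1], maf_range[2])

  ns <- structure$n_sires; k <- structure$offspring_per_sire
  nu <- structure$n_unrelated
  n_off <- ns * k

  dos <- matrix(NA_real_, n_off + nu, m)
  fam <- rep(NA_character_, n_off + nu)
  if (n_off > 0) {
    # sire haplotypes: ns x m, two gametes each
    s1 <- matrix(stats::rbinom(ns * m, 1, rep(q, each = ns)), ns, m)
    s2 <- matrix(stats::rbinom(ns * m, 1, rep(q, each = ns)), ns, m)
    sire_of <- rep(seq_len(ns), each = k)
    pick <- matrix(stats::rbinom(n_off * m, 1, 0.5), n_off, m)
    paternal <- s1[sire_of, , drop = FALSE] * pick +
      s2[sire_of, , drop = FALSE] * (1 - pick)
    maternal <- matrix(stats::rbinom(n_off * m, 1, rep(q, each = n_off)),
                       n_off, m)
    dos[seq_len(n_off), ] <- paternal + maternal
    fam[seq_len(n_off)] <- paste0("sire", sire_of)
  }
  if (nu > 0) {
    dos[n_off + seq_len(nu), ] <-
      matrix(stats::rbinom(nu * m, 1, rep(q, each = nu)), nu, m) +
      matrix(stats::rbinom(nu * m, 1, rep(q, each = nu)), nu, m)
  }
  rownames(dos) <- paste0("A", seq_len(nrow(dos)))

  chrom <- sort(rep_len(seq_len(n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    cumsum(sample(1000:100000, length(ix), replace = TRUE))), use.names = FALSE)
  pairs <- matrix(c("A", "C", "A", "G", "A", "T", "C", "G", "C", "T", "G", "T"),
                  ncol = 2, byrow = TRUE)
  pick_pair <- sample(nrow(pairs), m, replace = TRUE)
  map <- data.frame(marker = paste0("rs", seq_len(m)), chrom = chrom, pos = pos,
                    a1 = pairs[pick_pair, 1], a2 = pairs[pick_pair, 2],
                    stringsAsFactors = FALSE)
  colnames(dos) <- map$marker
  panel <- snp_panel(dos, map)
  attr(panel, "families") <- stats::setNames(fam, rownames(dos))
  attr(panel, "true_freqs") <- q
  panel
}

# symmetric square root of sigma2 * G with eigenvalue clipping at zero;
# finite-marker GRMs can carry tiny negative eigenvalues
grm_factor <- function(grm_obj, tol = 1e-6) {
  ee <- eigen(grm_obj$g, symmetric = TRUE)
  if (min(ee$values) < -tol * max(abs(ee$values)))
    stop("relationship matrix is not positive semi-definite within tolerance")
  vals <- pmax(ee$values, 0)
  list(u = ee$vectors, values = vals)
}

#' Simulate a polygenic trait under the genomic animal model
#'
#' Draws `y = X b + a + e` with `a ~ N(0, sigma_a2 * G)` (multivariate normal
#' via symmetric factorization of G, negative eigenvalues clipped at zero) and
#' i.i.d. residuals `e ~ N(0, sigma_e2)`. This is the generative inverse of
#' the model the REML fitter estimates, so parameter recovery is directly
#' testable.
#'
#' @param grm a [grm()] (positive semi-definite within tolerance).
#' @param design a [build_design()] result, or `NULL` for no fixed effects.
#' @param truth a [sim_truth()] carrying `sigma_a2`, `sigma_e2` and optional
#'   `fixed_effect_values` (recycled/padded to the design columns).
#' @param seed RNG seed.
#' @return a [trait_vector()] with the truth attached as attribute `"truth"`.
#' @export
simulate_polygenic_trait <- function(grm, design = NULL, truth, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  fac <- grm_factor(grm)
  n <- nrow(grm$g)
  set.seed(seed)
  a <- as.vector(fac$u %*% (sqrt(truth$sigma_a2 * fac$values) * stats::rnorm(n)))
  e <- stats::rnorm(n, 0, sqrt(truth$sigma_e2))
  fixed <- numeric(n)
  if (!is.null(design)) {
    X <- design$X[match(grm$sample_ids, design$sample_ids), , drop = FALSE]
    if (anyNA(X)) stop("design does not cover all grm samples")
    b <- truth$fixed_effect_values
    if (is.null(b)) b <- numeric(ncol(X))
    b <- rep_len(b, ncol(X))
    fixed <- as.vector(X %*% b)
  }
  y <- trait_vector(stats::setNames(fixed + a + e, grm$sample_ids),
                    transforms = list(list(type = "simulated", seed = seed)))
  attr(y, "truth") <- truth
  attr(y, "components") <- list(fixed = fixed, a = a, e = e)
  y
}

#' Simulate a trait with one causal marker plus polygenic background
#'
#' The causal allele-substitution effect is scaled so the marker explains the
#' requested fraction of total trait variance in expectation:
#' `beta^2 var(x) = f / (1 - f) * (sigma_a2 + sigma_e2)`. With
#' `variance_fraction = 0` the output reduces exactly to
#' [simulate_polygenic_trait()] under the same seed, because the marker term
#' consumes no random numbers.
#'
#' @param panel the [snp_panel()] containing the causal marker.
#' @param grm relationship matrix for the polygenic part.
#' @param causal_snp marker id.
#' @param variance_fraction fraction of trait variance for the marker, in
#'   \[0, 1).
#' @param truth a [sim_truth()] for the polygenic and residual parts.
#' @param seed RNG seed.
#' @param effect_sign +1 or -1.
#' @inherit simulate_polygenic_trait return
#' @export
simulate_qtl_trait <- function(panel, grm, causal_snp, variance_fraction,
                               truth, seed = 1, effect_sign = 1) {
  if (!causal_snp %in% panel$map$marker)
    stop("causal marker ", causal_snp, " not present in panel")
  if (variance_fraction < 0 || variance_fraction >= 1)
    stop("variance_fraction must lie in [0, 1)")
  x <- panel$dosages[, causal_snp]
  vx <- stats::var(x)
  if (variance_fraction > 0 && (is.na(vx) || vx == 0))
    stop("causal marker ", causal_snp, " is monomorphic")
  y <- simulate_polygenic_trait(grm, design = NULL, truth = truth, seed = seed)
  beta <- 0
  if (variance_fraction > 0) {
    beta <- effect_sign * sqrt(variance_fraction / (1 - variance_fraction) *
                                 (truth$sigma_a2 + truth$sigma_e2) / vx)
    xg <- x[match(grm$sample_ids, rownames(panel$dosages))]
    y[] <- as.numeric(y) + beta * xg  # [<- keeps class and transform log
  }
  tr <- attr(y, "truth")
  tr$causal_snp_ids <- causal_snp
  tr$causal_betas <- beta
  attr(y, "truth") <- tr
  y
}

#' Simulate a compositional count table with known basis correlations
#'
#' Latent ("basis") abundances are log-normal: per-taxon log means drawn once
#' from N(0, `log_mean_sd`^2), log deviations multivariate normal with the
#' requested correlation matrix and standard deviation `log_sd`. Counts are
#' multinomial draws of size `depth` from the closed fractions, so every row
#' sums to `depth` exactly. This matches the generative benchmark the SparCC
#' algorithm was designed for; a Dirichlet-multinomial option adds
#' overdispersion.
#'
#' @param n_samples,n_taxa table dimensions (`n_taxa >= 10`; the SparCC
#'   sparsity assumption needs many uncorrelated taxa).
#' @param depth sequencing depth per sample (>= 1).
#' @param basis_correlations `NULL` (independence), a full correlation
#'   matrix, or a data.frame with columns `i`, `j`, `r` planting individual
#'   pairs.
#' @param seed RNG seed.
#' @param log_mean_sd,log_sd spread of taxon log means and log-abundance
#'   standard deviation.
#' @param model `"lognormal"` (default) or `"dirichlet-multinomial"`.
#' @param dm_concentration total Dirichlet concentration for the
#'   overdispersed option.
#' @return a [taxon_table()]; truth (the correlation matrix used) attached as
#'   attribute `"truth"`.
#' @export
simulate_count_table <- function(n_samples, n_taxa, depth,
                                 basis_correlations = NULL, seed = 1,
                                 log_mean_sd = 1, log_sd = 1,
                                 model = c("lognormal", "dirichlet-multinomial"),
                                 dm_concentration = 500) {
  model <- match.arg(model)
  if (n_taxa < 10) stop("n_taxa must be >= 10")
  if (depth < 1) stop("depth must be >= 1")
  C <- diag(n_taxa)
  if (!is.null(basis_correlations)) {
    if (is.matrix(basis_correlations)) {
      C <- basis_correlations
    } else {
      bc <- as.data.frame(basis_correlations)
      for (k in seq_len(nrow(bc))) {
        C[bc$i[k], bc$j[k]] <- C[bc$j[k], bc$i[k]] <- bc$r[k]
      }
    }
  }
  ch <- tryCatch(chol(C), error = function(e)
    stop("requested basis correlation matrix is not positive definite"))
  set.seed(seed)
  mu <- stats::rnorm(n_taxa, 0, log_mean_sd)
  Z <- matrix(stats::rnorm(n_samples * n_taxa), n_samples, n_taxa) %*% ch
  latent <- exp(sweep(log_sd * Z, 2, mu, "+"))
  frac <- latent / rowSums(latent)
  counts <- matrix(0L, n_samples, n_taxa)
  for (i in seq_len(n_samples)) {
    p <- frac[i, ]
    if (model == "dirichlet-multinomial") {
      g <- stats::rgamma(n_taxa, shape = p * dm_concentration)
      p <- g / sum(g)
    }
    counts[i, ] <- stats::rmultinom(1, depth, p)[, 1]
  }
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                           paste0("T", seq_len(n_taxa)))
  tab <- taxon_table(counts)
  attr(tab, "truth") <- list(basis_correlations = C, seed = seed,
                             fractions = frac)
  tab
}

#' Simulate per-animal metadata and host phenotypes
#'
#' Emulates a multi-breed feedlot cohort record: breed (3 levels), sex
#' (bull/heifer/steer), diet (4 levels), age at sampling (days), metabolic
#' weight MWT (kg^0.75), average daily gain ADG (kg/day), dry matter intake
#' DMI generated as a linear function of MWT and ADG plus noise (so residual
#' feed intake has genuine signal to regress out), backfat (mm), and volatile
#' fatty acid measures (total mM plus acetate/propionate/butyrate/other molar
#' proportions that sum to one).
#'
#' @param n number of animals; ids default to `A1..An`.
#' @param seed RNG seed.
#' @param sample_ids optional explicit ids.
#' @return data.frame with one row per animal.
#' @export
simulate_metadata <- function(n, seed = 1, sample_ids = NULL) {
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- paste0("A", seq_len(n))
  breed <- sample(c("ANG", "CHAR", "HYB"), n, replace = TRUE,
                  prob = c(0.29, 0.16, 0.55))
  sex <- sample(c("bull", "heifer", "steer"), n, replace = TRUE,
                prob = c(0.10, 0.49, 0.41))
  diet <- sample(paste0("diet", 1:4), n, replace = TRUE)
  age <- round(stats::rnorm(n, 293, 10))
  mwt <- stats::rnorm(n, 85, 8)
  adg <- stats::rnorm(n, 1.5, 0.3)
  dmi <- 1.0 + 0.06 * mwt + 1.2 * adg + stats::rnorm(n, 0, 0.6)
  backfat <- stats::rnorm(n, 10, 2.5)
  vfa_total <- stats::rnorm(n, 100, 15)
  g <- cbind(stats::rgamma(n, 65), stats::rgamma(n, 20),
             stats::rgamma(n, 12), stats::rgamma(n, 3))
  prop <- g / rowSums(g)
  data.frame(sample = sample_ids, breed = breed, sex = sex, diet = diet,
             age = age, MWT = mwt, ADG = adg, DMI = dmi, backfat = backfat,
             vfa_total = vfa_total,
             acetate = prop[, 1], propionate = prop[, 2],
             butyrate = prop[, 3], other_vfa = prop[, 4],
             stringsAsFactors = FALSE)
}
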