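# Shared fixture builders: everything is generated in code at test time.

# tiny count table with a two-level lineage for collapse tests
toy_table <- function() {
  counts <- rbind(S1 = c(3, 4, 10, 3),
                  S2 = c(1, 0, 5, 14),
                  S3 = c(6, 2, 2, 10))
  colnames(counts) <- c("gA", "gB", "gC", "gD")
  lineage <- data.frame(
    phylum = c("P1", "P1", "P1", "P2"),
    family = c("F1", "F1", "F2", "F3"),
    genus = c("gA", "gB", NA, "gD"),
    row.names = c("gA", "gB", "gC", "gD"), stringsAsFactors = FALSE)
  taxon_table(counts, lineage)
}

# a small simulated cohort: genotypes, GRM, metadata, design
sim_cohort <- function(n_sires = 10, k = 10, n_unrel = 20, m = 500, seed = 1,
                       formula = ~ breed + sex + diet + age) {
  panel <- simulate_genotypes(pedigree_structure(n_sires, k, n_unrel), m,
                              seed = seed)
  G <- build_grm(panel)
  md <- simulate_metadata(nrow(panel$dosages), seed = seed + 1,
                          sample_ids = rownames(panel$dosages))
  list(panel = panel, G = G, md = md,
       design = build_design(md, formula))
}

# independent dense-matrix evaluation of the REML criterion (the oracle the
# eigen-rotated implementation is checked against)
dense_reml_loglik <- function(y, X, G, s2a, s2e) {
  n <- length(y); p <- ncol(X)
  V <- s2a * G + s2e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}

# brute-force Benjamini-Hochberg step-up (oracle for bh_fdr)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Procrustes error after optimal rotation/reflection (no scaling)
procrustes_error <- function(Y, X) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(t(Yc) %*% Xc)
  R <- sv$u %*% t(sv$v)
  sum((Yc %*% R - Xc)^2)
}

expect_seed_identical <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}

# simple taxonomy for simulated taxa: a few phyla/families, some taxa
# unclassified at genus
make_sim_lineage <- function(taxa, seed = 1) {
  set.seed(seed)
  n <- length(taxa)
  phylum <- sample(paste0("P", 1:4), n, replace = TRUE)
  family <- paste0(phylum, "_F", sample(1:3, n, replace = TRUE))
  genus <- taxa
  genus[sample(n, max(1, n %/% 5))] <- NA
  data.frame(phylum = phylum, family = family, genus = genus,
             row.names = taxa, stringsAsFactors = FALSE)
}

# write a complete pipeline input fixture; returns the config paths
build_pipeline_fixture <- function(dir, n = 120, m = 400, n_taxa = 30,
                                   depth = 3000, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_genotypes(pedigree_structure(n %/% 10, 10, n %% 10), m,
                              seed = seed)
  # plant a couple of QC failures
  panel$dosages[, 1] <- rbinom(nrow(panel$dosages), 2, 0.02)
  panel$dosages[1:ceiling(0.2 * n), 2] <- NA
  ids <- rownames(panel$dosages)
  tab <- simulate_count_table(n, n_taxa, depth, seed = seed + 1)
  rownames(tab$counts) <- ids
  tab <- taxon_table(tab$counts, make_sim_lineage(colnames(tab$counts),
                                                  seed = seed + 2))
  md <- simulate_metadata(n, seed = seed + 3, sample_ids = ids)
  counts_path <- file.path(dir, "counts.tsv")
  write_count_table(tab, counts_path)
  md_path <- file.path(dir, "metadata.tsv")
  utils::write.table(md, md_path, sep = "\t", quote = FALSE, row.names = FALSE)
  geno_prefix <- file.path(dir, "geno")
  write_genotypes(panel, geno_prefix, dialect = "dosage-tsv")
  list(counts = counts_path,
       lineage = file.path(dir, "counts.lineage.tsv"),
       metadata = md_path, genotypes = geno_prefix)
}
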