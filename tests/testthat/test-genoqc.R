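test_that("HWE chi-square matches hand-computed expectations", {
  r <- hwe_test(25, 50, 25)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  r2 <- hwe_test(50, 0, 50)
  expect_equal(r2$chisq, 100)  # expected (25, 50, 25): 25 + 50 + 25
  expect_lt(r2$p, 1e-6)
  r3 <- hwe_test(100, 0, 0)
  expect_equal(r3$chisq, 0)
  expect_equal(r3$p, 1)
  expect_error(hwe_test(0, 0, 0), "no genotyped")
})

test_that("SNP QC removes exactly the planted violations with reasons", {
  set.seed(13)
  n <- 200
  good <- rbinom(n, 2, 0.3)
  low_maf <- rbinom(n, 2, 0.04)
  while (mean(low_maf) / 2 >= 0.05) low_maf <- rbinom(n, 2, 0.03)
  low_cr <- rbinom(n, 2, 0.4); low_cr[1:30] <- NA          # 85% call rate
  hwe_bad <- sample(rep(c(0, 2), each = n / 2))             # no heterozygotes
  dos <- cbind(good = good, low_maf = low_maf, low_cr = low_cr,
               hwe_bad = hwe_bad)
  rownames(dos) <- paste0("A", 1:n)
  map <- data.frame(marker = colnames(dos), chrom = 1, pos = 1:4 * 1000,
                    a1 = "A", a2 = "C")
  qc <- qc_snps(snp_panel(dos, map))
  expect_identical(colnames(qc$panel$dosages), "good")
  expect_setequal(qc$report$marker[qc$report$criterion == "MAF"], "low_maf")
  expect_setequal(qc$report$marker[qc$report$criterion == "call rate"], "low_cr")
  expect_true("hwe_bad" %in% qc$report$marker[qc$report$criterion == "HWE"])
  expect_equal(qc$n_input, 4)
  expect_equal(qc$n_retained, 1)
  # idempotent on a panel that already passes
  qc2 <- qc_snps(qc$panel)
  expect_identical(qc2$panel$dosages, qc$panel$dosages)
  expect_equal(nrow(qc2$report), 0)
})

test_that("imputation fills missing dosages from observed calls", {
  dos <- cbind(m1 = c(0, 2, NA, 2), m2 = c(1, 1, 1, 1))
  rownames(dos) <- paste0("A", 1:4)
  map <- data.frame(marker = c("m1", "m2"), chrom = 1, pos = c(1, 2),
                    a1 = "A", a2 = "C")
  panel <- snp_panel(dos, map)
  imp <- impute_missing(panel)
  expect_equal(unname(imp$dosages[3, "m1"]), 2 * (4 / 6))  # 2 x observed freq
  # no missing values: identity
  full <- impute_missing(snp_panel(dos[, 2, drop = FALSE],
                                   map[2, , drop = FALSE]))
  expect_equal(full$dosages, dos[, 2, drop = FALSE])
  # random imputation is seeded and converges to observed frequencies
  set.seed(21)
  big <- matrix(rbinom(5000, 2, 0.3), 5000, 1,
                dimnames = list(paste0("A", 1:5000), "mm"))
  obs_freq <- table(factor(big[1:2000], levels = 0:2)) / 2000
  big[2001:5000, 1] <- NA
  big[1:2000, 1] <- big[1:2000, 1]
  pan <- snp_panel(big, data.frame(marker = "mm", chrom = 1, pos = 1,
                                   a1 = "A", a2 = "C"))
  r1 <- impute_missing(pan, method = "random", seed = 5)
  r2 <- impute_missing(pan, method = "random", seed = 5)
  expect_identical(r1$dosages, r2$dosages)
  imp_freq <- table(factor(r1$dosages[2001:5000], levels = 0:2)) / 3000
  expect_lt(max(abs(imp_freq - obs_freq)), 0.03)
  # fully missing marker is an error
  allna <- matrix(NA_real_, 3, 1, dimnames = list(paste0("A", 1:3), "bad"))
  expect_error(impute_missing(snp_panel(allna,
                                        data.frame(marker = "bad", chrom = 1,
                                                   pos = 1, a1 = "A", a2 = "C"))),
               "bad")
})

test_that("VanRaden GRM matches hand computations and its invariances", {
  # all-heterozygous individual at p = 0.5: centered row is zero -> diag 0
  dos <- rbind(A1 = c(1, 1, 1, 1), A2 = c(2, 2, 2, 2), A3 = c(0, 0, 0, 0),
               A4 = c(2, 2, 2, 2))
  colnames(dos) <- paste0("m", 1:4)
  map <- data.frame(marker = colnames(dos), chrom = 1, pos = 1:4,
                    a1 = "A", a2 = "C")
  panel <- snp_panel(dos, map)
  G <- build_grm(panel, allele_freqs = rep(0.5, 4))
  expect_equal(G$g["A1", "A1"], 0)
  # two individuals homozygous for the same allele at every marker, p = 0.5:
  # Z rows are +/-1 -> diag 2, off-diag 2 within a homozygote class
  expect_equal(G$g["A2", "A2"], 2)
  expect_equal(G$g["A3", "A3"], 2)
  expect_equal(G$g["A2", "A4"], 2)   # same-allele homozygotes
  expect_equal(G$g["A2", "A3"], -2)  # opposite-allele homozygotes
  expect_true(isSymmetric(G$g))

  # marker order and allele-label flips leave G unchanged
  ch <- sim_cohort(n_sires = 5, k = 6, n_unrel = 20, m = 200, seed = 31)
  perm <- sample(200)
  map_perm <- ch$panel$map[perm, ]
  map_perm$chrom <- 1
  map_perm$pos <- seq_len(200) * 10
  Gp <- build_grm(snp_panel(ch$panel$dosages[, perm], map_perm))
  expect_equal(Gp$g, ch$G$g, tolerance = 1e-12)
  flip <- ch$panel
  flip$dosages <- 2 - flip$dosages
  Gf <- build_grm(flip)
  expect_equal(Gf$g, ch$G$g, tolerance = 1e-12)

  # unrelated HWE population: trace/n -> 1 at large m
  pu <- simulate_genotypes(pedigree_structure(0, 0, 200), 10000, seed = 9)
  Gu <- build_grm(pu)
  expect_lt(abs(mean(diag(Gu$g)) - 1), 0.02)

  mono <- matrix(2, 3, 2, dimnames = list(paste0("A", 1:3), c("x", "y")))
  expect_error(build_grm(snp_panel(mono, data.frame(marker = c("x", "y"),
                                                    chrom = 1, pos = 1:2,
                                                    a1 = "A", a2 = "C"))),
               "monomorphic")
})
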