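test_that("genotype simulation is seed-deterministic and HWE-consistent", {
  st <- pedigree_structure(5, 4, 10)
  p1 <- simulate_genotypes(st, 200, seed = 11)
  p2 <- simulate_genotypes(st, 200, seed = 11)
  expect_identical(p1, p2)
  p3 <- simulate_genotypes(st, 200, seed = 12)
  expect_false(identical(p1$dosages, p3$dosages))

  # fixed allele frequency 0.5, unrelated: mean dosage near HWE expectation 1
  p <- simulate_genotypes(pedigree_structure(0, 0, 10000), 1,
                          maf_range = c(0.5, 0.5), seed = 3)
  se <- sqrt(2 * 0.25 / 10000)
  expect_lt(abs(mean(p$dosages) - 1), 3 * se)

  # unrelated genotypes pass the HWE test at 1e-6 for >= 99.9% of markers
  pu <- simulate_genotypes(pedigree_structure(0, 0, 500), 2000, seed = 4)
  st2 <- microherit:::marker_stats(pu$dosages)
  expect_gte(mean(st2$hwe_p > 1e-6), 0.999)

  expect_error(simulate_genotypes(pedigree_structure(0, 0, 10), 100,
                                  maf_range = c(0.001, 0.5)), "maf_range")
  expect_error(pedigree_structure(0, 0, 0), "at least one")
})

test_that("half-sib families show the expected VanRaden relationship", {
  panel <- simulate_genotypes(pedigree_structure(50, 10, 100), 2000, seed = 7)
  G <- build_grm(panel)
  fam <- attr(panel, "families")
  same <- outer(fam, fam, function(a, b) !is.na(a) & !is.na(b) & a == b)
  ut <- upper.tri(G$g)
  # expected additive relationship of paternal half sibs is 0.25
  expect_lt(abs(mean(G$g[same & ut]) - 0.25), 0.05)
  diff_fam <- !same
  expect_lt(abs(mean(G$g[diff_fam & ut])), 0.05)
})

test_that("polygenic trait simulation respects its variance components", {
  ch <- sim_cohort(n_sires = 0, k = 0, n_unrel = 650, m = 800, seed = 21)
  # degenerate case: no genetic variance -> phenotypic variance ~ sigma_e2
  y0 <- simulate_polygenic_trait(ch$G, NULL, sim_truth(0, 2), seed = 5)
  expect_lt(abs(var(as.numeric(y0)) - 2), 4 * 2 * sqrt(2 / 650))

  # Monte-Carlo covariance check: sigma_e2 -> 0, y ~ N(0, sigma_a2 G)
  reps <- sapply(1:300, function(i)
    as.numeric(simulate_polygenic_trait(
      grm(ch$G$g[1:8, 1:8]), NULL, sim_truth(1.5, 1e-10), seed = 1000 + i)))
  emp <- cov(t(reps))
  expect_lt(max(abs(emp - 1.5 * ch$G$g[1:8, 1:8])), 0.6)

  # variance bookkeeping: fixed + a + e reproduce the requested totals
  tru <- sim_truth(0.4, 0.6, fixed_effect_values = rep(0.2, ncol(ch$design$X)))
  y <- simulate_polygenic_trait(ch$G, ch$design, tru, seed = 31)
  comp <- attr(y, "components")
  expect_lt(abs(var(comp$a) - 0.4 * mean(diag(ch$G$g))), 0.12)
  expect_lt(abs(var(comp$e) - 0.6), 0.12)
  expect_equal(as.numeric(y), comp$fixed + comp$a + comp$e)

  expect_error(simulate_polygenic_trait(grm(diag(5) * -1), NULL,
                                        sim_truth(1, 1)), "semi-definite")
})

test_that("QTL trait scales the causal effect to the requested fraction", {
  ch <- sim_cohort(n_sires = 20, k = 10, n_unrel = 0, m = 300, seed = 41)
  causal <- ch$panel$map$marker[100]
  tru <- sim_truth(0.25, 0.75)
  # variance_fraction = 0 reduces exactly to the polygenic draw
  y0 <- simulate_qtl_trait(ch$panel, ch$G, causal, 0, tru, seed = 8)
  yp <- simulate_polygenic_trait(ch$G, NULL, tru, seed = 8)
  expect_equal(as.numeric(y0), as.numeric(yp))

  # effect-sign symmetry: estimated beta flips sign, magnitude comparable
  yplus <- simulate_qtl_trait(ch$panel, ch$G, causal, 0.10, tru, seed = 9,
                              effect_sign = 1)
  yminus <- simulate_qtl_trait(ch$panel, ch$G, causal, 0.10, tru, seed = 9,
                               effect_sign = -1)
  sp <- mixed_model_scan(yplus, ch$panel, ch$G)
  sm <- mixed_model_scan(yminus, ch$panel, ch$G)
  bp <- sp$beta[sp$marker == causal]; bm <- sm$beta[sm$marker == causal]
  expect_gt(bp, 0)
  expect_lt(bm, 0)
  sep <- sp$se_beta[sp$marker == causal]
  expect_lt(abs(abs(bp) - abs(bm)), 2 * sep)

  # monomorphic causal marker is rejected
  mono_panel <- ch$panel
  mono_panel$dosages[, 1] <- 2
  expect_error(simulate_qtl_trait(mono_panel, ch$G, mono_panel$map$marker[1],
                                  0.05, tru), "monomorphic")
})

test_that("count-table simulation closes rows and honours the seed", {
  tab <- simulate_count_table(40, 15, 500, seed = 3)
  expect_true(all(rowSums(tab$counts) == 500))
  tab2 <- simulate_count_table(40, 15, 500, seed = 3)
  expect_identical(tab$counts, tab2$counts)
  expect_error(simulate_count_table(10, 5, 100), "n_taxa")
  # non-positive-definite request is refused
  bad <- diag(12); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(simulate_count_table(20, 12, 100, basis_correlations = bad),
               "positive definite")
  # dirichlet-multinomial option still closes rows
  tabdm <- simulate_count_table(20, 12, 300, seed = 4,
                                model = "dirichlet-multinomial")
  expect_true(all(rowSums(tabdm$counts) == 300))
})
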