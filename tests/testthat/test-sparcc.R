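test_that("basis-variance solver is exact on a closed-form case", {
  # three log-abundance vectors with diagonal sample covariance: the
  # variation matrix is t_ij = v_i + v_j exactly, the sparsity system
  # recovers the basis variances, and all correlations vanish
  set.seed(41)
  raw <- matrix(rnorm(60), 20, 3)
  # columns orthonormal and orthogonal to the constant vector => exactly
  # centered with a diagonal sample covariance
  ortho <- qr.Q(qr(cbind(1, raw)))[, 2:4]
  lf <- ortho %*% diag(c(1, 2, 3))
  est <- microherit:::sparcc_once(lf, exclusion_threshold = 0.1,
                                  max_exclusion_rounds = 0)
  expect_lt(max(abs(est$r[upper.tri(est$r)])), 1e-8)
  expect_equal(diag(est$r), rep(1, 3))
})

test_that("SparCC recovers planted structure and stays near zero under the null", {
  null_tab <- simulate_count_table(100, 50, 2000, seed = 141)
  spn <- sparcc_correlations(null_tab, seed = 142)
  expect_lte(mean(abs(spn$r[upper.tri(spn$r)])), 0.1)
  expect_true(all(abs(spn$r) <= 1))
  expect_equal(unname(diag(spn$r)), rep(1, 50))
  expect_lt(max(abs(spn$r - t(spn$r))), 1e-12)

  planted <- simulate_count_table(100, 50, 2000,
                                  basis_correlations = data.frame(i = 1, j = 2,
                                                                  r = 0.7),
                                  seed = 143)
  sp <- sparcc_correlations(planted, pseudocount_mode = "add-one")
  expect_gt(sp$r[1, 2], 0.4)
  expect_gt(sp$r[1, 2], max(abs(sp$r[upper.tri(sp$r)] [-1])) - 1e-12)

  expect_error(sparcc_correlations(simulate_count_table(30, 10, 200)$counts[, 1:3]),
               "4 taxa")
  expect_error(sparcc_correlations(null_tab$counts[, 1:8]), "10 taxa")
})

test_that("per-sample rescaling barely moves add-one SparCC estimates", {
  # an even community (no very rare taxa), so the +1 pseudocount is small
  # relative to every count
  tab <- simulate_count_table(60, 20, 2000, seed = 151, log_mean_sd = 0.3)
  r1 <- sparcc_correlations(tab, pseudocount_mode = "add-one")$r
  r2 <- sparcc_correlations(tab$counts * 5L, pseudocount_mode = "add-one")$r
  # log-ratio variances are total-invariant; only the +1 pseudocount shifts
  expect_lt(max(abs(r1 - r2)), 0.05)
})

test_that("permutation p-values are bounded, seeded, and detect planted pairs", {
  planted <- simulate_count_table(80, 20, 1000,
                                  basis_correlations = data.frame(i = 1, j = 2,
                                                                  r = 0.8),
                                  seed = 161)
  sp <- sparcc_correlations(planted, inner_iterations = 5, seed = 162)
  sp <- sparcc_pvalues(planted, sp, permutations = 200, seed = 163,
                       inner_iterations = 2)
  expect_true(all(sp$p[upper.tri(sp$p)] >= 1 / 201))
  expect_equal(sp$p[1, 2], 1 / 201)  # separation: minimum attainable value
  sp2 <- sparcc_pvalues(planted, sparcc_correlations(planted,
                                                     inner_iterations = 5,
                                                     seed = 162),
                        permutations = 200, seed = 163, inner_iterations = 2)
  expect_identical(sp$p, sp2$p)
  expect_error(sparcc_pvalues(planted, sp, permutations = 0), "permutations")
})

test_that("network edges respect the strict |r| and p thresholds", {
  ids <- paste0("T", 1:4)
  r <- diag(4); p <- matrix(1, 4, 4)
  r[1, 2] <- r[2, 1] <- 0.35;  p[1, 2] <- p[2, 1] <- 5e-4
  r[1, 3] <- r[3, 1] <- 0.25;  p[1, 3] <- p[3, 1] <- 1e-6
  r[2, 4] <- r[4, 2] <- -0.5;  p[2, 4] <- p[4, 2] <- 9e-4
  r[3, 4] <- r[4, 3] <- 0.6;   p[3, 4] <- p[4, 3] <- 0.001  # p not < 0.001
  res <- structure(list(taxon_ids = ids, r = r, p = p),
                   class = "sparcc_result")
  edges <- build_network(res)
  expect_equal(nrow(edges), 2)
  e1 <- edges[edges$taxon_a == "T1", ]
  expect_equal(e1$sign, "positive")
  e2 <- edges[edges$taxon_a == "T2", ]
  expect_equal(e2$sign, "negative")
  expect_error(build_network(structure(list(taxon_ids = ids, r = r, p = NULL),
                                       class = "sparcc_result")),
               "p-values")
})

test_that("network prefilter subsamples once and drops sparse taxa", {
  set.seed(171)
  counts <- matrix(rpois(50 * 12, 60), 50, 12,
                   dimnames = list(paste0("S", 1:50), paste0("T", 1:12)))
  counts[, 12] <- 0
  counts[1:7, 12] <- 50          # 14% prevalence: eliminated
  counts[1, ] <- 0; counts[1, 1] <- 100   # shallow sample: removed
  tab <- taxon_table(counts)
  out <- prefilter_for_network(tab, depth = 300, seed = 172)
  expect_false("T12" %in% colnames(out$counts))
  expect_false("S1" %in% rownames(out$counts))
  expect_true(all(rowSums(out$counts) == 300))
})
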