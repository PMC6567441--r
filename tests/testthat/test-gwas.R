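test_that("phenotype adjustment returns OLS residuals orthogonal to the design", {
  ch <- sim_cohort(n_sires = 6, k = 8, n_unrel = 12, m = 200, seed = 101)
  # trait exactly in the design span: residuals are zero
  y_lin <- trait_vector(setNames(as.numeric(ch$design$X %*% rep(1, ncol(ch$design$X))),
                                 ch$design$sample_ids))
  adj <- adjust_phenotype(y_lin, ch$design)
  expect_lt(max(abs(adj), na.rm = TRUE), 1e-10)

  # intercept-only: mean centering
  int_des <- structure(list(X = matrix(1, 60, 1,
                                       dimnames = list(ch$design$sample_ids[1:60],
                                                       "(Intercept)")),
                            sample_ids = ch$design$sample_ids[1:60],
                            dropped_columns = character()),
                       class = "fe_design")
  v <- setNames(rnorm(60), ch$design$sample_ids[1:60])
  adj2 <- adjust_phenotype(trait_vector(v), int_des)
  expect_equal(as.numeric(adj2[names(v)]), unname(v - mean(v)),
               tolerance = 1e-12)

  # one-factor design equals group-mean centering (hand oracle)
  md <- data.frame(sample = paste0("s", 1:6),
                   grp = c("a", "a", "a", "b", "b", "b"))
  des <- build_design(md, ~ grp)
  tv <- trait_vector(setNames(c(1, 2, 3, 10, 11, 15), md$sample))
  adj3 <- adjust_phenotype(tv, des)
  expect_equal(unname(as.numeric(adj3)), c(1, 2, 3, 10, 11, 15) -
                 rep(c(2, 12), each = 3), tolerance = 1e-12)
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(des$X) %*% as.numeric(adj3[des$sample_ids]))), 1e-8)
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_identical(bh_fdr(numeric()), numeric())
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_lt(max(abs(bh_fdr(p) - brute_bh(p))), 1e-12)
  }
  # idempotent on its own output's order statistics
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p - 1e-15))
})

test_that("association tiers use the printed strict inequalities", {
  expect_equal(classify_association(c(0.006, 0.17, 0.25, 0.1, 0.2)),
               c("significant", "suggestive", "none", "none", "none"))
})

test_that("the scan reduces to per-marker OLS when the genetic variance is zero", {
  ch <- sim_cohort(n_sires = 10, k = 8, n_unrel = 20, m = 60, seed = 111)
  y <- simulate_polygenic_trait(ch$G, NULL, sim_truth(0.2, 0.8), seed = 112)
  scan <- mixed_model_scan(y, ch$panel, ch$G, lambda = 0)
  ids <- ch$G$sample_ids
  for (j in sample(60, 10)) {
    mk <- ch$panel$map$marker[j]
    x <- ch$panel$dosages[ids, mk] - 1
    sm <- summary(lm(as.numeric(y[ids]) ~ x))$coefficients
    row <- scan[scan$marker == mk, ]
    expect_equal(row$beta, sm[2, 1], tolerance = 1e-8)
    expect_equal(row$se_beta, sm[2, 2], tolerance = 1e-8)
    expect_equal(row$p_value, sm[2, 4], tolerance = 1e-8)
  }
})

test_that("genotype recoding flips effect signs but not p-values", {
  ch <- sim_cohort(n_sires = 10, k = 8, n_unrel = 20, m = 80, seed = 121)
  y <- simulate_polygenic_trait(ch$G, NULL, sim_truth(0.25, 0.75), seed = 122)
  scan <- mixed_model_scan(y, ch$panel, ch$G)
  flip <- ch$panel
  flip$dosages <- 2 - flip$dosages
  # same relationship matrix, markers recoded: only the sign convention of
  # beta may change
  scan_f <- mixed_model_scan(y, flip, ch$G)
  ord <- match(scan$marker, scan_f$marker)
  expect_equal(scan_f$beta[ord], -scan$beta, tolerance = 1e-10)
  expect_equal(scan_f$p_value[ord], scan$p_value, tolerance = 1e-10)
})

test_that("P3D and exact modes agree closely and flag monomorphic markers", {
  ch <- sim_cohort(n_sires = 10, k = 10, n_unrel = 30, m = 60, seed = 131)
  panel <- ch$panel
  panel$dosages[, 5] <- 2  # monomorphic
  G <- build_grm(panel)
  y <- simulate_qtl_trait(panel, G, panel$map$marker[20], 0.08,
                          sim_truth(0.25, 0.75), seed = 132)
  p3d <- mixed_model_scan(y, panel, G, mode = "P3D")
  exact <- mixed_model_scan(y, panel, G, mode = "exact")
  poly <- !p3d$monomorphic
  ord <- match(p3d$marker, exact$marker)
  expect_gt(cor(p3d$p_value[poly], exact$p_value[ord][poly],
                method = "spearman"), 0.99)
  mono_row <- p3d[p3d$monomorphic, ]
  expect_equal(nrow(mono_row), 1)
  expect_equal(mono_row$beta, 0)
  expect_equal(mono_row$p_value, 1)
  # unmapped markers stay out of the scan
  panel2 <- ch$panel
  panel2$map$chrom[1:10] <- NA
  scan2 <- mixed_model_scan(y, panel2, G)
  expect_equal(nrow(scan2), 50)
  # records arrive sorted by chromosome then position
  expect_true(!is.unsorted(order(scan2$chrom, scan2$pos)))
  expect_true(all(diff(scan2$pos[scan2$chrom == scan2$chrom[1]]) >= 0))
})
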