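test_that("fixed-effects design uses treatment coding and drops aliased columns", {
  md <- simulate_metadata(120, seed = 51)
  des <- build_design(md)
  # 1 + (3-1) + (3-1) + (4-1) + 1 = 9 columns
  expect_equal(ncol(des$X), 9)
  expect_equal(qr(des$X)$rank, 9)

  # a factor perfectly confounded with another loses its aliased columns
  md2 <- md
  md2$dup <- md$sex
  expect_warning(des2 <- build_design(md2, ~ sex + dup + age), "aliased")
  expect_equal(qr(des2$X)$rank, ncol(des2$X))

  # permuting sample order leaves the per-sample fitted structure unchanged
  md3 <- md[sample(nrow(md)), ]
  des3 <- build_design(md3)
  expect_equal(des3$X[des$sample_ids, colnames(des$X)], des$X,
               ignore_attr = TRUE)

  expect_warning(build_design(cbind(md, const = 1), ~ breed + const),
                 "zero-variance")
  expect_error(build_design(md[0, ]), "no samples")
})

test_that("heritability ratio and classification follow their definitions", {
  expect_equal(heritability(1, 3), 0.25)
  expect_equal(heritability(0, 2), 0)
  expect_gt(heritability(2, 1e-12), 1 - 1e-9)
  expect_error(heritability(-1, 1))
  expect_error(heritability(0, 0))

  fit <- structure(list(h2 = 0.16, converged = TRUE), class = "animal_reml")
  expect_equal(classify_heritable(fit), "heritable")
  fit$h2 <- 0.149
  expect_equal(classify_heritable(fit), "not heritable")
  fit$h2 <- 0.15
  expect_equal(classify_heritable(fit), "heritable")  # inclusive threshold
  fit$converged <- FALSE
  expect_error(classify_heritable(fit), "not converged")

  expect_equal(gwas_eligible(structure(list(h2 = 0.1, converged = TRUE),
                                       class = "animal_reml")), TRUE)
  expect_equal(gwas_eligible(structure(list(h2 = 0.05, converged = TRUE),
                                       class = "animal_reml")), FALSE)
})

test_that("eigen-rotated restricted likelihood equals the dense evaluation", {
  set.seed(61)
  maxd <- 0
  for (k in 1:5) {
    n <- sample(60:180, 1)
    ch <- sim_cohort(n_sires = 8, k = n %/% 8, n_unrel = n %% 8, m = 300,
                     seed = 60 + k, formula = ~ breed + sex + age)
    y <- simulate_polygenic_trait(ch$G, ch$design, sim_truth(0.3, 0.7),
                                  seed = 70 + k)
    s2a <- runif(1, 0.05, 1); s2e <- runif(1, 0.1, 1)
    a <- reml_loglik(y, ch$design, ch$G, s2a, s2e)
    ids <- ch$design$sample_ids
    b <- dense_reml_loglik(as.numeric(y[ids]), ch$design$X,
                           ch$G$g[ids, ids], s2a, s2e)
    maxd <- max(maxd, abs(a - b))
  }
  expect_lt(maxd, 1e-6)
})

test_that("the profile optimum dominates a grid and the fit is equivariant", {
  ch <- sim_cohort(n_sires = 10, k = 12, n_unrel = 30, m = 400, seed = 81)
  y <- simulate_polygenic_trait(ch$G, ch$design, sim_truth(0.4, 0.6), seed = 82)
  fit <- fit_animal_model(y, ch$design, ch$G)
  expect_true(fit$converged)
  expect_equal(fit$h2, fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2),
               tolerance = 1e-10)

  # restricted log-likelihood at the optimum beats any of 50 grid points
  grid <- c(0, 10^seq(-4, 4, length.out = 49))
  ll_grid <- vapply(grid, function(l)
    reml_loglik(y, ch$design, ch$G, l * fit$sigma_e2, fit$sigma_e2), 0)
  expect_gte(fit$loglik_reml + 1e-6, max(ll_grid))

  # scale equivariance: y * c multiplies variances by c^2, h2 unchanged
  y2 <- trait_vector(setNames(as.numeric(y) * 2, names(y)))
  fit2 <- fit_animal_model(y2, ch$design, ch$G)
  # agreement is limited by the flatness of the profile near its optimum
  expect_equal(fit2$h2, fit$h2, tolerance = 1e-7)
  expect_equal(fit2$sigma_a2, 4 * fit$sigma_a2, tolerance = 1e-6)
  expect_equal(fit2$sigma_e2, 4 * fit$sigma_e2, tolerance = 1e-6)

  # adding a constant moves only the intercept
  y3 <- trait_vector(setNames(as.numeric(y) + 5, names(y)))
  fit3 <- fit_animal_model(y3, ch$design, ch$G)
  expect_equal(fit3$sigma_a2, fit$sigma_a2, tolerance = 1e-6)
  expect_equal(coef(fit3)[["(Intercept)"]],
               coef(fit)[["(Intercept)"]] + 5, tolerance = 1e-6)
  expect_equal(coef(fit3)[-1], coef(fit)[-1], tolerance = 1e-6)

  # a null trait lands at or near the h2 = 0 boundary
  y0 <- simulate_polygenic_trait(ch$G, NULL, sim_truth(0, 1), seed = 83)
  fit0 <- fit_animal_model(y0, NULL, ch$G)
  expect_lt(fit0$h2, 0.2)

  # identity-proportional relationship matrix is not identifiable
  gi <- grm(diag(length(y)), n_markers_used = 1)
  rownames(gi$g) <- colnames(gi$g) <- names(y)
  gi$sample_ids <- names(y)
  expect_error(fit_animal_model(y, ch$design, gi), "identity")
})

test_that("heritability screen assembles one row per feature", {
  ch <- sim_cohort(n_sires = 8, k = 8, n_unrel = 16, m = 300, seed = 91)
  feats <- sapply(1:3, function(i)
    as.numeric(simulate_polygenic_trait(ch$G, NULL, sim_truth(0.3, 0.7),
                                        seed = 90 + i)))
  rownames(feats) <- ch$G$sample_ids
  colnames(feats) <- paste0("f", 1:3)
  tab <- heritability_screen(feats, ch$design, ch$G)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$converged))
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 1))
  expect_identical(tab$heritable, tab$h2 >= 0.15)
})
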