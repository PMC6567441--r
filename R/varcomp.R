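# The genomic animal model: y = X beta + a + e, a ~ N(0, sigma_a2 G),
# e ~ N(0, sigma_e2 I), fitted by REML via a single spectral decomposition of
# G and a one-dimensional profile search over the variance ratio
# lambda = sigma_a2 / sigma_e2. With one genetic variance component this is
# exact and globally searchable (the EMMA idea), unlike iterative AI-REML.

#' Build a fixed-effects design
#'
#' Treatment (reference-level) coding of the factors plus covariates, with
#' rank inspection: columns aliased by nesting (e.g. a diet fed to only one
#' sex) are detected via QR and dropped with a warning, as are zero-variance
#' covariates. Rows with any missing factor level or covariate are dropped
#' (the animal model uses only animals with complete records).
#'
#' @param metadata data.frame with a `sample` id column.
#' @param formula RHS-only formula naming factors/covariates, default
#'   `~ breed + sex + diet + age`.
#' @return object of class `fe_design`: list with `X` (full-column-rank
#'   design matrix, rownames = sample ids), `sample_ids`,
#'   `dropped_columns`, `formula`.
#' @export
build_design <- function(metadata, formula = ~ breed + sex + diet + age) {
  metadata <- as.data.frame(metadata)
  if (!"sample" %in% names(metadata)) stop("metadata needs a 'sample' column")
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(metadata))
  if (length(missing_vars))
    stop("metadata lacks: ", paste(missing_vars, collapse = ", "))
  complete <- stats::complete.cases(metadata[, vars, drop = FALSE])
  md <- metadata[complete, , drop = FALSE]
  if (!nrow(md)) stop("no samples with complete fixed-effect records")
  for (v in vars) if (is.character(md[[v]])) md[[v]] <- factor(md[[v]])
  dropped <- character()
  # zero-variance covariates carry no information and break scaling
  for (v in vars) {
    col <- md[[v]]
    if (is.numeric(col) && stats::sd(col) == 0) {
      warning("dropping zero-variance covariate: ", v)
      dropped <- c(dropped, v)
    }
    if (is.factor(col) && nlevels(droplevels(col)) < 2) {
      warning("dropping single-level factor: ", v)
      dropped <- c(dropped, v)
    }
  }
  keep_vars <- setdiff(vars, dropped)
  f <- stats::reformulate(if (length(keep_vars)) keep_vars else "1")
  X <- stats::model.matrix(f, data = md)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping aliased design columns: ",
            paste(aliased, collapse = ", "))
    dropped <- c(dropped, aliased)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  rownames(X) <- as.character(md$sample)
  structure(list(X = X, sample_ids = as.character(md$sample),
                 dropped_columns = dropped, formula = formula),
            class = "fe_design")
}

#' @export
print.fe_design <- function(x, ...) {
  cat("fe_design:", nrow(x$X), "samples x", ncol(x$X), "columns (",
      paste(colnames(x$X), collapse = ", "), ")\n")
  if (length(x$dropped_columns))
    cat("  dropped:", paste(x$dropped_columns, collapse = ", "), "\n")
  invisible(x)
}

# align trait, design, grm on shared non-missing samples and eigendecompose
prepare_mixed <- function(trait, design, grm_obj, min_n = 30) {
  ids <- names(trait)[!is.na(trait)]
  ids <- intersect(ids, grm_obj$sample_ids)
  if (!is.null(design)) ids <- intersect(ids, design$sample_ids)
  n <- length(ids)
  if (n < min_n) stop("only ", n, " usable samples; need >= ", min_n)
  y <- as.numeric(trait[ids])
  X <- if (is.null(design)) {
    matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  } else {
    design$X[ids, , drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design rank-deficient after subsetting; dropping: ",
            paste(aliased, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  G <- grm_obj$g[ids, ids]
  ee <- eigen(G, symmetric = TRUE)
  if (min(ee$values) < -1e-6 * max(abs(ee$values)))
    stop("relationship matrix not positive semi-definite within tolerance")
  s <- pmax(ee$values, 0)
  if (max(s) - min(s) < 1e-8 * max(s, 1))
    stop("relationship matrix proportional to identity: ",
         "genetic and residual variances are not separable")
  list(ids = ids, n = n, y = y, X = X,
       u = ee$vectors, s = s,
       ys = crossprod(ee$vectors, y),
       Xs = crossprod(ee$vectors, X))
}

# restricted log-likelihood core in the eigenbasis, for covariance
# sigma_a2 * G + sigma_e2 * I; d = sigma_a2 * s + sigma_e2.
# lR = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
reml_core <- function(ys, Xs, d) {
  n <- length(ys); p <- ncol(Xs)
  w <- 1 / d
  XtWX <- crossprod(Xs, Xs * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys * w)))
  r <- ys - Xs %*% beta
  quad <- sum(w * r^2)
  ll <- -0.5 * ((n - p) * log(2 * pi) + sum(log(d)) +
                  2 * sum(log(diag(ch))) + quad)
  list(ll = as.numeric(ll), beta = beta, quad = quad, rss = quad)
}

# profile restricted likelihood over lambda with sigma_e2 profiled out
profile_ll <- function(lambda, prep) {
  n <- prep$n; p <- ncol(prep$Xs)
  d <- lambda * prep$s + 1
  w <- 1 / d
  XtWX <- crossprod(prep$Xs, prep$Xs * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(prep$Xs, prep$ys * w)))
  r <- prep$ys - prep$Xs %*% beta
  rss <- sum(w * r^2)
  s2e <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) + (n - p) +
            sum(log(d)) + 2 * sum(log(diag(ch))))
}

#' Restricted log-likelihood of the animal model at given variances
#'
#' Evaluates the REML criterion
#' `-1/2 [(n-p) log 2pi + log|V| + log|X' V^-1 X| + y' P y]` with
#' `V = sigma_a2 G + sigma_e2 I`, computed in the eigenbasis of G. Useful for
#' verifying the fit against a direct dense-matrix evaluation.
#'
#' @param trait,design,grm as in [fit_animal_model()].
#' @param sigma_a2,sigma_e2 variance components (`sigma_e2 > 0`).
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(trait, design, grm, sigma_a2, sigma_e2) {
  prep <- prepare_mixed(trait, design, grm)
  reml_core(prep$ys, prep$Xs, sigma_a2 * prep$s + sigma_e2)$ll
}

#' Fit the genomic animal model by spectral REML
#'
#' Estimates `sigma_a2`, `sigma_e2` and heritability
#' `h2 = sigma_a2 / (sigma_a2 + sigma_e2)` for one trait. G is
#' eigendecomposed once; the restricted likelihood is profiled over the
#' variance ratio on a log-spaced grid spanning \[1e-5, 1e5\] and refined by
#' bounded golden-section search; the variance components are then recovered
#' in closed form. The standard error of `h2` comes from the delta method on
#' the numerical curvature of the profile restricted likelihood in the `h2`
#' parameterization (an approximation to, not a replication of,
#' average-information SEs). Optima pinned at `h2 = 0` or `h2 = 1` set the
#' `boundary` flag.
#'
#' @param trait a [trait_vector()] or named numeric; `NA`s are dropped.
#' @param design a [build_design()] result, or `NULL` for intercept-only.
#' @param grm a [grm()].
#' @param n_grid grid points for the initial lambda sweep.
#' @param min_n minimum usable sample count (default 30).
#' @return object of class `animal_reml` with elements `sigma_a2`,
#'   `sigma_e2`, `h2`, `se_h2`, `loglik_reml`, `n_used`, `converged`,
#'   `boundary`, `beta` (fixed-effect solutions), `lambda`.
#' @export
fit_animal_model <- function(trait, design = NULL, grm, n_grid = 64,
                             min_n = 30) {
  prep <- prepare_mixed(trait, design, grm, min_n = min_n)
  n <- prep$n; p <- ncol(prep$Xs)

  log_grid <- seq(-5, 5, length.out = n_grid)
  lambdas <- c(0, 10^log_grid)
  lls <- vapply(lambdas, profile_ll, 0, prep = prep)
  best <- which.max(lls)
  if (!is.finite(lls[best])) stop("restricted likelihood not evaluable")

  if (best == 1) {
    # interior refinement between 0 and the smallest grid value
    opt <- stats::optimize(function(l) profile_ll(l, prep),
                           interval = c(0, 10^log_grid[1]), maximum = TRUE,
                           tol = 1e-10)
    lambda_hat <- if (opt$objective > lls[1] + 1e-10) opt$maximum else 0
  } else {
    lo <- if (best == 2) 0 else 10^log_grid[best - 2]
    hi <- if (best == length(lambdas)) 10^log_grid[n_grid] else
      10^log_grid[best]
    opt <- stats::optimize(function(l) profile_ll(l, prep),
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
    lambda_hat <- opt$maximum
    if (lls[best] > opt$objective) lambda_hat <- lambdas[best]
  }

  d <- lambda_hat * prep$s + 1
  w <- 1 / d
  XtWX <- crossprod(prep$Xs, prep$Xs * w)
  beta <- solve(XtWX, crossprod(prep$Xs, prep$ys * w))
  r <- prep$ys - prep$Xs %*% beta
  s2e <- sum(w * r^2) / (n - p)
  s2a <- lambda_hat * s2e
  h2 <- if (s2a + s2e > 0) s2a / (s2a + s2e) else 0
  boundary <- h2 < 1e-4 || h2 > 1 - 1e-4 ||
    lambda_hat >= 10^log_grid[n_grid] * 0.999

  # delta-method SE from profile curvature in the h2 parameterization
  f_h <- function(h) {
    h <- min(max(h, 0), 1 - 1e-8)
    profile_ll(h / (1 - h), prep)
  }
  step <- 1e-3
  h0 <- min(max(h2, 0), 1 - 2 * step)
  if (h0 < step) {
    f0 <- f_h(0); f1 <- f_h(step); f2 <- f_h(2 * step)
    curv <- (f2 - 2 * f1 + f0) / step^2
  } else {
    curv <- (f_h(h0 + step) - 2 * f_h(h0) + f_h(h0 - step)) / step^2
  }
  se_h2 <- if (is.finite(curv) && curv < 0) sqrt(-1 / curv) else NA_real_

  ll <- reml_core(prep$ys, prep$Xs, s2a * prep$s + s2e)$ll
  structure(list(sigma_a2 = s2a, sigma_e2 = s2e, h2 = h2, se_h2 = se_h2,
                 loglik_reml = ll, n_used = n, converged = TRUE,
                 boundary = boundary, lambda = lambda_hat,
                 beta = stats::setNames(as.numeric(beta), colnames(prep$Xs)),
                 sample_ids = prep$ids),
            class = "animal_reml")
}

#' @export
print.animal_reml <- function(x, ...) {
  cat(sprintf("animal model REML fit (n = %d)\n", x$n_used))
  cat(sprintf("  sigma_a2 = %.4g  sigma_e2 = %.4g\n", x$sigma_a2, x$sigma_e2))
  cat(sprintf("  h2 = %.3f (SE %.3f)%s\n", x$h2, x$se_h2,
              if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' @export
summary.animal_reml <- function(object, ...) {
  out <- c(object[c("sigma_a2", "sigma_e2", "h2", "se_h2", "loglik_reml",
                    "n_used", "converged", "boundary")])
  class(out) <- "summary.animal_reml"
  attr(out, "beta") <- object$beta
  out
}

#' @export
print.summary.animal_reml <- function(x, ...) {
  cat("Genomic animal model (REML via spectral decomposition)\n")
  cat(sprintf("  n used: %d | converged: %s | boundary: %s\n",
              x$n_used, x$converged, x$boundary))
  cat(sprintf("  sigma_a2 = %.6g\n  sigma_e2 = %.6g\n", x$sigma_a2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f  (SE %.4f)\n", x$h2, x$se_h2))
  cat(sprintf("  restricted logLik = %.4f\n", x$loglik_reml))
  cat("  fixed effects:\n")
  print(round(attr(x, "beta"), 4))
  invisible(x)
}

#' @export
coef.animal_reml <- function(object, ...) object$beta

#' @export
logLik.animal_reml <- function(object, ...) {
  structure(object$loglik_reml, df = 2, class = "logLik")
}

#' Narrow-sense heritability from variance components
#'
#' @param sigma_a2 additive-genetic variance (>= 0).
#' @param sigma_e2 residual variance (> 0).
#' @return `sigma_a2 / (sigma_a2 + sigma_e2)`, in \[0, 1\].
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  if (sigma_a2 < 0) stop("sigma_a2 must be >= 0")
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  sigma_a2 / (sigma_a2 + sigma_e2)
}

#' Classify a fitted feature as heritable
#'
#' Heritable iff `h2 >= threshold` (inclusive; default 0.15).
#'
#' @param fit an `animal_reml` fit (must have converged).
#' @param threshold heritability cutoff.
#' @return `"heritable"` or `"not heritable"`.
#' @export
classify_heritable <- function(fit, threshold = 0.15) {
  if (!isTRUE(fit$converged)) stop("classification refused: fit not converged")
  if (fit$h2 >= threshold) "heritable" else "not heritable"
}

#' Heritability screen over many features
#'
#' Fits the animal model per column of a feature matrix and assembles the
#' machine-readable analog of a heritability results table.
#'
#' @param features samples x features numeric matrix (NA allowed).
#' @param design,grm as in [fit_animal_model()].
#' @param threshold heritable cutoff for the `heritable` column.
#' @param min_n minimum usable samples per feature; features below are
#'   skipped with `NA` rows.
#' @return data.frame: feature, n_used, sigma_a2, sigma_e2, h2, se_h2,
#'   converged, boundary, heritable.
#' @export
heritability_screen <- function(features, design, grm, threshold = 0.15,
                                min_n = 30) {
  features <- as.matrix(features)
  rows <- lapply(colnames(features), function(f) {
    tr <- stats::setNames(features[, f], rownames(features))
    fit <- tryCatch(fit_animal_model(tr, design, grm, min_n = min_n),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(feature = f, n_used = NA, sigma_a2 = NA,
                        sigma_e2 = NA, h2 = NA, se_h2 = NA, converged = FALSE,
                        boundary = NA, heritable = NA))
    }
    data.frame(feature = f, n_used = fit$n_used, sigma_a2 = fit$sigma_a2,
               sigma_e2 = fit$sigma_e2, h2 = fit$h2, se_h2 = fit$se_h2,
               converged = fit$converged, boundary = fit$boundary,
               heritable = fit$h2 >= threshold)
  })
  do.call(rbind, rows)
}
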