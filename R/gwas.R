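# Single-marker mixed-model association on fixed-effect-adjusted traits.
# Default mode is P3D: the variance ratio is estimated once under the
# no-marker null and reused for every marker test (the behavior of standard
# genomic-association packages); "exact" re-profiles per marker.

#' Adjust a trait for fixed effects
#'
#' Ordinary least-squares residuals of the trait on the design matrix,
#' computed on non-missing samples; residuals are orthogonal to every design
#' column. Missing samples stay missing.
#'
#' @param trait [trait_vector()] or named numeric.
#' @param design a [build_design()] result.
#' @return a [trait_vector()] of residuals.
#' @export
adjust_phenotype <- function(trait, design) {
  ids <- intersect(names(trait)[!is.na(trait)], design$sample_ids)
  if (!length(ids)) stop("no shared non-missing samples")
  X <- design$X[ids, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design rank-deficient on these samples; aliased columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  res <- stats::setNames(rep(NA_real_, length(trait)), names(trait))
  res[ids] <- qr.resid(qrX, as.numeric(trait[ids]))
  trait_vector(res, transforms = c(attr(trait, "transforms"),
                                   list(list(type = "fixed_effect_adjustment",
                                             columns = colnames(X)))))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement, applied within one
#' trait's scan. A thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector in (0, 1\].
#' @return FDR-adjusted values of the same length (empty in, empty out).
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  stats::p.adjust(p_values, method = "BH")
}

#' Tier an association by its FDR
#'
#' Significant iff `fdr < 0.1`; suggestive iff `0.1 < fdr < 0.2`; otherwise
#' none. Strict inequalities, so `fdr = 0.1` exactly is "none".
#'
#' @param fdr numeric vector of FDR values.
#' @return character vector: `"significant"`, `"suggestive"`, or `"none"`.
#' @export
classify_association <- function(fdr) {
  ifelse(fdr < 0.1, "significant",
         ifelse(fdr > 0.1 & fdr < 0.2, "suggestive", "none"))
}

#' Eligibility of a feature for the association scan
#'
#' Features enter GWAS when their heritability estimate reaches `threshold`
#' (inclusive; default 0.1).
#'
#' @param fit converged `animal_reml` fit.
#' @param threshold heritability cutoff.
#' @export
gwas_eligible <- function(fit, threshold = 0.1) {
  if (!isTRUE(fit$converged)) stop("fit not converged")
  fit$h2 >= threshold
}

#' Single-marker mixed-model association scan
#'
#' For each mapped marker, a generalized least-squares test of the additive
#' marker effect under covariance `sigma_a2 G + sigma_e2 I`. Genotypes are
#' coded -1/0/1 for aa/Aa/AA. In `"P3D"` mode the variance ratio is profiled
#' once under the marker-free null (grand mean only, since the trait is
#' already fixed-effect adjusted) and reused; `"exact"` mode re-profiles the
#' ratio per marker. p-values come from the t distribution of
#' `beta / se_beta` on `n - 2` degrees of freedom (mean + marker).
#' Monomorphic markers are emitted with `beta = 0`, `p = 1` and flagged.
#' Markers without a known chromosome/position are excluded from the scan
#' (they still participate in the relationship matrix).
#'
#' @param adjusted fixed-effect-adjusted trait ([adjust_phenotype()]).
#' @param panel complete [snp_panel()].
#' @param grm a [grm()].
#' @param mode `"P3D"` or `"exact"`.
#' @param lambda optional fixed variance ratio `sigma_a2 / sigma_e2`
#'   overriding estimation (`lambda = 0` reduces every test to plain OLS).
#' @param fdr_within `"scan"` applies BH across the scan's p-values.
#' @return data.frame of class `gwas_scan`, sorted by chromosome and
#'   position: marker, chrom, pos, beta, se_beta, p_value, fdr, tier,
#'   monomorphic.
#' @export
mixed_model_scan <- function(adjusted, panel, grm, mode = c("P3D", "exact"),
                             lambda = NULL, fdr_within = "scan") {
  mode <- match.arg(mode)
  if (anyNA(panel$dosages)) stop("panel has missing dosages; impute first")
  mapped <- !is.na(panel$map$chrom) & !is.na(panel$map$pos)
  map <- panel$map[mapped, , drop = FALSE]

  prep <- prepare_mixed(adjusted, design = NULL, grm_obj = grm)
  ids <- prep$ids
  n <- prep$n
  M <- panel$dosages[ids, map$marker, drop = FALSE] - 1  # -1/0/1 coding

  if (is.null(lambda)) {
    if (mode == "P3D") {
      null_fit <- fit_animal_model(adjusted, design = NULL, grm = grm)
      lambda0 <- null_fit$lambda
    }
  } else {
    lambda0 <- lambda
    mode <- "P3D"  # a fixed ratio is by definition population-parameters-once
  }

  mono <- apply(M, 2, function(x) stats::var(x) == 0)
  beta <- se <- pval <- rep(NA_real_, ncol(M))

  if (mode == "P3D") {
    d <- lambda0 * prep$s + 1
    w <- 1 / d
    ys <- prep$ys[, 1]
    one_s <- prep$Xs[, 1]  # rotated intercept (design is intercept-only here)
    Ms <- crossprod(prep$u, M)
    a11 <- sum(w * one_s^2)
    b1 <- sum(w * one_s * ys)
    yWy <- sum(w * ys^2)
    a12 <- colSums((w * one_s) * Ms)
    a22 <- colSums(w * Ms^2)
    b2 <- colSums((w * ys) * Ms)
    det <- a11 * a22 - a12^2
    bm <- (a11 * b2 - a12 * b1) / det
    bmu <- (b1 * a22 - a12 * b2) / det
    rss <- yWy - (bmu * b1 + bm * b2)
    rss <- pmax(rss, 0)
    s2 <- rss / (n - 2)
    vb <- s2 * a11 / det
    beta <- bm
    se <- sqrt(pmax(vb, 0))
    tt <- beta / se
    pval <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    y <- stats::setNames(prep$y, ids)
    for (j in seq_len(ncol(M))) {
      if (mono[j]) next
      Xj <- cbind(`(Intercept)` = 1, marker = M[, j])
      rownames(Xj) <- ids
      dj <- structure(list(X = Xj, sample_ids = ids,
                           dropped_columns = character(),
                           formula = ~marker), class = "fe_design")
      fitj <- fit_animal_model(y, dj, grm)
      lamj <- fitj$lambda
      d <- lamj * prep$s + 1
      w <- 1 / d
      Xs <- crossprod(prep$u, Xj)
      XtWX <- crossprod(Xs, Xs * w)
      XtWy <- crossprod(Xs, prep$ys * w)
      bb <- solve(XtWX, XtWy)
      r <- prep$ys - Xs %*% bb
      s2 <- sum(w * r^2) / (n - 2)
      vb <- s2 * solve(XtWX)[2, 2]
      beta[j] <- bb[2]
      se[j] <- sqrt(max(vb, 0))
      pval[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), df = n - 2)
    }
  }

  beta[mono] <- 0
  se[mono] <- NA_real_
  pval[mono] <- 1

  out <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    beta = beta, se_beta = se, p_value = pval,
                    monomorphic = mono, stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p_value)
  out$tier <- classify_association(out$fdr)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("gwas_scan", "data.frame")
  attr(out, "lambda") <- if (mode == "P3D") lambda0 else NA_real_
  attr(out, "mode") <- mode
  attr(out, "n_used") <- n
  out
}
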