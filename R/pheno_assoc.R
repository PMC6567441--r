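# Derived host traits (FCR, RFI, log ratios) and the Spearman screen of
# heritable microbial features against feed-efficiency and fermentation
# measures.

#' Log-ratio feature between two abundances
#'
#' `log10(x) - log10(y)` per shared sample (i.e. the log of the ratio, with
#' both parts log10-transformed before the ratio is formed). Non-positive
#' inputs yield a missing value with a warning.
#'
#' @param x,y [trait_vector()]s or named numerics on overlapping samples.
#' @return a [trait_vector()] on the shared samples.
#' @export
log_ratio_feature <- function(x, y) {
  ids <- intersect(names(x), names(y))
  if (!length(ids)) stop("no shared samples")
  xv <- as.numeric(x[ids]); yv <- as.numeric(y[ids])
  bad <- !is.na(xv) & !is.na(yv) & (xv <= 0 | yv <= 0)
  if (any(bad)) warning(sum(bad), " sample(s) with non-positive values set missing")
  out <- ifelse(!is.na(xv) & !is.na(yv) & xv > 0 & yv > 0,
                log10(xv) - log10(yv), NA_real_)
  trait_vector(stats::setNames(out, ids),
               transforms = list(list(type = "log10_ratio")))
}

#' Feed conversion ratio
#'
#' `FCR = DMI / ADG` (dry matter intake over average daily gain). Animals
#' with non-positive ADG get a missing value with a warning.
#'
#' @param dmi,adg numeric vectors (kg/day).
#' @export
compute_fcr <- function(dmi, adg) {
  bad <- !is.na(adg) & adg <= 0
  if (any(bad)) warning(sum(bad), " animal(s) with ADG <= 0 set missing")
  out <- dmi / adg
  out[bad] <- NA_real_
  out
}

#' Residual feed intake
#'
#' Residuals of the least-squares regression of DMI on ADG and metabolic
#' weight; when `backfat` is supplied the backfat-adjusted variant (RFIf) is
#' returned as well. Residuals sum to zero and are orthogonal to the
#' regressors. This within-cohort regression is a simplified form of the
#' production RFI calculation, which additionally standardizes test periods.
#'
#' @param dmi,adg,mwt numeric vectors with >= 10 complete records.
#' @param backfat optional backfat thickness (mm) for RFIf.
#' @return list with `rfi` (and `rfif` when backfat is given), `NA` where
#'   records are incomplete.
#' @export
compute_rfi <- function(dmi, adg, mwt, backfat = NULL) {
  n <- length(dmi)
  base_df <- data.frame(dmi = dmi, adg = adg, mwt = mwt)
  cc <- stats::complete.cases(base_df)
  if (sum(cc) < 10) stop("need >= 10 animals with complete DMI/ADG/MWT records")
  X <- cbind(1, adg[cc], mwt[cc])
  if (qr(X)$rank < ncol(X)) stop("collinear regressors in RFI model")
  fit <- stats::lm.fit(X, dmi[cc])
  rfi <- rep(NA_real_, n)
  rfi[cc] <- fit$residuals
  out <- list(rfi = rfi)
  if (!is.null(backfat)) {
    cc2 <- cc & !is.na(backfat)
    if (sum(cc2) < 10) stop("need >= 10 complete records for RFIf")
    X2 <- cbind(1, adg[cc2], mwt[cc2], backfat[cc2])
    if (qr(X2)$rank < ncol(X2)) stop("collinear regressors in RFIf model")
    rfif <- rep(NA_real_, n)
    rfif[cc2] <- stats::lm.fit(X2, dmi[cc2])$residuals
    out$rfif <- rfif
  }
  out
}

# average-rank Spearman rho with t-approximation p, pairwise complete
spearman_one <- function(x, y, method = "t", permutations = 10000,
                         seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 5) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      p <- max(p, .Machine$double.xmin)
    }
  } else {
    set.seed(seed)
    null <- replicate(permutations, stats::cor(rank(x), rank(sample(y))))
    p <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (1 + permutations)
  }
  c(rho = rho, p = p, n = n)
}

#' Spearman correlation screen
#'
#' Average-rank Spearman correlations of every feature against every trait,
#' with pairwise-complete sample handling. p-values by the t approximation
#' (adequate at the cohort sizes this package targets) or by random
#' permutation for small n.
#'
#' @param features samples x features matrix (NA allowed).
#' @param traits samples x traits matrix, rows aligned by rownames.
#' @param p_threshold significance flag cutoff.
#' @param method `"t"` or `"permutation"`.
#' @param permutations,seed permutation settings.
#' @return object of class `correlation_screen`: list with `rho`, `p`, `n`
#'   matrices (features x traits) and `long`, a long-format data.frame
#'   (feature, trait, rho, p, n, significant).
#' @export
spearman_screen <- function(features, traits, p_threshold = 0.05,
                            method = c("t", "permutation"),
                            permutations = 10000, seed = 1) {
  method <- match.arg(method)
  features <- as.matrix(features); traits <- as.matrix(traits)
  ids <- intersect(rownames(features), rownames(traits))
  if (length(ids) < 5) stop("fewer than 5 shared samples")
  features <- features[ids, , drop = FALSE]
  traits <- traits[ids, , drop = FALSE]
  nf <- ncol(features); nt <- ncol(traits)
  rho <- p <- nmat <- matrix(NA_real_, nf, nt,
                             dimnames = list(colnames(features), colnames(traits)))
  for (i in seq_len(nf)) for (j in seq_len(nt)) {
    res <- spearman_one(features[, i], traits[, j], method = method,
                        permutations = permutations, seed = seed)
    rho[i, j] <- res["rho"]; p[i, j] <- res["p"]; nmat[i, j] <- res["n"]
  }
  long <- data.frame(feature = rep(colnames(features), nt),
                     trait = rep(colnames(traits), each = nf),
                     rho = as.vector(rho), p = as.vector(p),
                     n = as.vector(nmat),
                     significant = as.vector(p) < p_threshold,
                     stringsAsFactors = FALSE)
  structure(list(rho = rho, p = p, n = nmat, long = long,
                 p_threshold = p_threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("correlation_screen:", nrow(x$rho), "features x", ncol(x$rho), "traits;",
      sum(x$long$significant, na.rm = TRUE), "significant at p <",
      x$p_threshold, "\n")
  invisible(x)
}

#' Select heritable features from a heritability table
#'
#' @param fits data.frame from [heritability_screen()] (columns `feature`,
#'   `h2`, `converged`).
#' @param threshold inclusive heritability cutoff (default 0.15).
#' @return character vector of feature ids.
#' @export
select_heritable_features <- function(fits, threshold = 0.15) {
  if (!nrow(fits)) return(character())
  ok <- !is.na(fits$h2) & fits$converged & fits$h2 >= threshold
  fits$feature[ok]
}
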