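# SNP quality control, imputation, and VanRaden genomic relationship matrix.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square of observed genotype counts against the
#' Hardy-Weinberg expectation at the observed allele frequency. A
#' monomorphic marker has no testable departure: statistic 0, p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return list with `chisq` and `p`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("no genotyped individuals")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(list(chisq = 0, p = 1))
  e <- n * c(p^2, 2 * p * q, q^2)
  o <- c(n_AA, n_Aa, n_aa)
  chisq <- sum((o - e)^2 / e)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

marker_stats <- function(dosages) {
  n <- nrow(dosages)
  call_rate <- colMeans(!is.na(dosages))
  n_obs <- colSums(!is.na(dosages))
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  freq[n_obs == 0] <- NA
  maf <- pmin(freq, 1 - freq)
  nAA <- colSums(dosages == 2, na.rm = TRUE)
  nAa <- colSums(dosages == 1, na.rm = TRUE)
  naa <- colSums(dosages == 0, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(dosages)), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_test(nAA[j], nAa[j], naa[j])$p
  }, 0)
  data.frame(marker = colnames(dosages), call_rate = call_rate, freq = freq,
             maf = maf, hwe_p = hwe_p, stringsAsFactors = FALSE)
}

#' SNP quality control
#'
#' Retains markers with HWE chi-square p > `hwe_p_min`, minor allele
#' frequency >= `maf_min`, and call rate >= `callrate_min` (the standard
#' reading of removal criteria "HWE p <= 1e-6, MAF < 5%, call rate < 90%").
#' The removal report lists every failed criterion per removed marker.
#'
#' @param panel a [snp_panel()].
#' @param hwe_p_min,maf_min,callrate_min thresholds.
#' @return list with `panel` (filtered) and `report` (data.frame: marker,
#'   criterion, value; zero rows when nothing is removed).
#' @export
qc_snps <- function(panel, hwe_p_min = 1e-6, maf_min = 0.05,
                    callrate_min = 0.90) {
  if (!nrow(panel$map)) stop("empty panel")
  st <- marker_stats(panel$dosages)
  fail_hwe <- !is.na(st$hwe_p) & st$hwe_p <= hwe_p_min
  fail_maf <- is.na(st$maf) | st$maf < maf_min
  fail_cr <- st$call_rate < callrate_min
  mk_rows <- function(markers, criterion, values)
    data.frame(marker = markers, criterion = rep(criterion, length(markers)),
               value = values, stringsAsFactors = FALSE)
  report <- rbind(
    mk_rows(st$marker[fail_hwe], "HWE", st$hwe_p[fail_hwe]),
    mk_rows(st$marker[fail_maf], "MAF", st$maf[fail_maf]),
    mk_rows(st$marker[fail_cr], "call rate", st$call_rate[fail_cr]))
  keep <- !(fail_hwe | fail_maf | fail_cr)
  filtered <- snp_panel(panel$dosages[, keep, drop = FALSE],
                        panel$map[keep, , drop = FALSE])
  list(panel = filtered, report = report,
       n_input = nrow(st), n_retained = sum(keep))
}

#' Impute missing genotypes
#'
#' `"mean"` (default) replaces a missing dosage by twice the marker's
#' observed allele frequency (deterministic, adequate at low missingness);
#' `"random"` draws from the marker's observed genotype frequencies under a
#' seed. Provenance is recorded in an `"imputation"` attribute.
#'
#' @param panel a [snp_panel()]; every marker needs >= 1 observed call.
#' @param method `"mean"` or `"random"`.
#' @param seed RNG seed for `"random"`.
#' @return completed [snp_panel()].
#' @export
impute_missing <- function(panel, method = c("mean", "random"), seed = 1) {
  method <- match.arg(method)
  dos <- panel$dosages
  n_obs <- colSums(!is.na(dos))
  if (any(n_obs == 0))
    stop("fully missing marker(s): ",
         paste(colnames(dos)[n_obs == 0], collapse = ", "))
  miss_idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(miss_idx)) {
    if (method == "mean") {
      fill <- colMeans(dos, na.rm = TRUE)
      dos[miss_idx] <- fill[miss_idx[, 2]]
    } else {
      set.seed(seed)
      for (j in unique(miss_idx[, 2])) {
        obs <- dos[!is.na(dos[, j]), j]
        rows <- miss_idx[miss_idx[, 2] == j, 1]
        dos[rows, j] <- sample(obs, length(rows), replace = TRUE)
      }
    }
  }
  out <- list(dosages = dos, map = panel$map)
  class(out) <- "snp_panel"
  attr(out, "imputation") <- list(method = method, n_imputed = nrow(miss_idx),
                                  seed = if (method == "random") seed else NA)
  out
}

#' Build the VanRaden genomic relationship matrix
#'
#' Method 1: `Z = M - 2p` (dosages centered by twice the allele frequency),
#' `G = Z Z' / (2 sum p_k (1 - p_k))`. Frequencies default to the observed
#' post-QC data; an explicit vector can be supplied (e.g. to reproduce
#' textbook hand calculations). Invariant to marker order and to flipping
#' which allele is counted.
#'
#' @param panel complete (imputed) [snp_panel()] with >= 2 polymorphic
#'   markers.
#' @param allele_freqs optional per-marker frequencies for centering.
#' @return a [grm()].
#' @export
build_grm <- function(panel, allele_freqs = NULL) {
  M <- panel$dosages
  if (anyNA(M)) stop("panel has missing dosages; impute first")
  p <- if (is.null(allele_freqs)) colMeans(M) / 2 else allele_freqs
  if (length(p) != ncol(M)) stop("allele_freqs length mismatch")
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers monomorphic: zero VanRaden denominator")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  grm(G, n_markers_used = ncol(M), allele_freqs = p)
}
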