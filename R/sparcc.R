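# SparCC: correlation inference for compositional count data. Log-ratio
# variances t_ij = var(log(x_i/x_j)) are invariant to per-sample totals; under
# a sparsity assumption (most taxa uncorrelated) the basis variances omega
# solve a linear system in the row sums of T, and correlations follow as
# r_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j)). Strongly
# correlated pairs are iteratively excluded from the system and the whole
# estimate is the median over inner iterations that resample fractions from
# the posterior Dirichlet of each sample's counts.

# one estimate of the correlation matrix from a matrix of log fractions
sparcc_once <- function(logfrac, exclusion_threshold, max_exclusion_rounds) {
  D <- ncol(logfrac)
  V <- stats::cov(logfrac)
  vars <- diag(V)
  T <- outer(vars, vars, "+") - 2 * V  # t_ij = var(log x_i - log x_j)
  diag(T) <- 0

  M <- matrix(1, D, D)
  diag(M) <- D - 1
  t_row <- rowSums(T)
  excluded <- matrix(FALSE, D, D)
  rounds <- 0L
  r <- diag(D)
  repeat {
    omega <- tryCatch(solve(M, t_row), error = function(e) rep(NA_real_, D))
    if (anyNA(omega)) break
    omega <- pmax(omega, .Machine$double.eps)
    r <- (outer(omega, omega, "+") - T) / (2 * sqrt(outer(omega, omega)))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    if (rounds >= max_exclusion_rounds) break
    cand <- abs(r)
    cand[excluded] <- 0
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    t_row[i] <- t_row[i] - T[i, j]
    t_row[j] <- t_row[j] - T[i, j]
    rounds <- rounds + 1L
  }
  list(r = r, rounds = rounds)
}

sparcc_fractions <- function(counts, pseudocount_mode) {
  if (pseudocount_mode == "dirichlet") {
    # posterior draw with add-one prior, per sample
    g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
                nrow(counts), ncol(counts))
    g / rowSums(g)
  } else {
    f <- counts + 1
    f / rowSums(f)
  }
}

#' SparCC compositional correlations
#'
#' @param table a [taxon_table()] (or counts matrix) with >= 10 taxa and
#'   positive sample totals.
#' @param inner_iterations number of fraction-resampling iterations; the
#'   final correlation is the elementwise median across them. With
#'   `pseudocount_mode = "add-one"` the fractions are deterministic and one
#'   iteration suffices.
#' @param exclusion_threshold pairs whose |correlation| exceeds this are
#'   candidates for exclusion from the basis-variance system (strongest pair
#'   first, one per round).
#' @param max_exclusion_rounds cap on exclusion rounds.
#' @param pseudocount_mode `"dirichlet"` (posterior draw, default) or
#'   `"add-one"` (deterministic fractions, exactly compositional-invariant).
#' @param seed RNG seed for the Dirichlet draws.
#' @return object of class `sparcc_result`: `taxon_ids`, `r` (symmetric,
#'   unit diagonal), `p` (`NULL` until [sparcc_pvalues()]),
#'   `n_exclusion_rounds_run`.
#' @export
sparcc_correlations <- function(table, inner_iterations = 20,
                                exclusion_threshold = 0.1,
                                max_exclusion_rounds = 10,
                                pseudocount_mode = c("dirichlet", "add-one"),
                                seed = 1) {
  pseudocount_mode <- match.arg(pseudocount_mode)
  counts <- if (inherits(table, "taxon_table")) table$counts else as.matrix(table)
  D <- ncol(counts)
  if (D < 4) stop("SparCC basis system is underdetermined below 4 taxa")
  if (D < 10) stop("need >= 10 taxa for the sparsity assumption")
  if (any(rowSums(counts) == 0)) stop("zero-total sample(s) present")
  if (pseudocount_mode == "add-one") inner_iterations <- 1L
  set.seed(seed)
  rs <- array(NA_real_, c(D, D, inner_iterations))
  rounds <- integer(inner_iterations)
  for (it in seq_len(inner_iterations)) {
    f <- sparcc_fractions(counts, pseudocount_mode)
    est <- sparcc_once(log(f), exclusion_threshold, max_exclusion_rounds)
    rs[, , it] <- est$r
    rounds[it] <- est$rounds
  }
  r <- apply(rs, c(1, 2), stats::median)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(colnames(counts), colnames(counts))
  structure(list(taxon_ids = colnames(counts), r = r, p = NULL,
                 n_exclusion_rounds_run = max(rounds),
                 settings = list(inner_iterations = inner_iterations,
                                 exclusion_threshold = exclusion_threshold,
                                 max_exclusion_rounds = max_exclusion_rounds,
                                 pseudocount_mode = pseudocount_mode,
                                 seed = seed)),
            class = "sparcc_result")
}

#' @export
print.sparcc_result <- function(x, ...) {
  cat("sparcc_result:", length(x$taxon_ids), "taxa |",
      if (is.null(x$p)) "p-values not computed" else "p-values filled", "\n")
  invisible(x)
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation independently shuffles every taxon's counts across
#' samples (destroying all between-taxon association while preserving each
#' taxon's marginal distribution) and recomputes the correlations with the
#' observed run's settings. Two-sided add-one p-values:
#' `p_ij = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + permutations)`, so the
#' smallest attainable value is `1 / (permutations + 1)`.
#'
#' @param table the same table `observed` was computed from.
#' @param observed a [sparcc_correlations()] result.
#' @param permutations number of permutations (>= 1).
#' @param seed RNG seed; permutation b uses child seed `seed + b`.
#' @param inner_iterations inner iterations per permutation (defaults to the
#'   observed run's setting; smaller values trade precision of each null
#'   draw for speed).
#' @return the `sparcc_result` with `p` filled.
#' @export
sparcc_pvalues <- function(table, observed, permutations = 10000, seed = 1,
                           inner_iterations = NULL) {
  if (permutations < 1) stop("permutations must be >= 1")
  counts <- if (inherits(table, "taxon_table")) table$counts else as.matrix(table)
  st <- observed$settings
  if (is.null(inner_iterations)) inner_iterations <- st$inner_iterations
  n <- nrow(counts)
  robs <- abs(observed$r)
  exceed <- matrix(0, ncol(counts), ncol(counts))
  for (b in seq_len(permutations)) {
    set.seed(seed + b)
    perm <- apply(counts, 2, function(col) col[sample.int(n)])
    rp <- sparcc_correlations(perm, inner_iterations = inner_iterations,
                              exclusion_threshold = st$exclusion_threshold,
                              max_exclusion_rounds = st$max_exclusion_rounds,
                              pseudocount_mode = st$pseudocount_mode,
                              seed = seed + b)$r
    exceed <- exceed + (abs(rp) >= robs)
  }
  p <- (1 + exceed) / (1 + permutations)
  p <- (p + t(p)) / 2
  dimnames(p) <- dimnames(observed$r)
  observed$p <- p
  observed$permutations <- permutations
  observed
}

#' Build the co-occurrence edge list
#'
#' Edges exactly where `|r| > r_threshold` and `p < p_threshold` (both
#' strict).
#'
#' @param result a [sparcc_result] with p-values filled.
#' @param r_threshold,p_threshold edge filter.
#' @return data.frame: taxon_a, taxon_b, r, p, sign (possibly zero rows).
#' @export
build_network <- function(result, r_threshold = 0.3, p_threshold = 0.001) {
  if (is.null(result$p)) stop("p-values not filled; run sparcc_pvalues first")
  D <- length(result$taxon_ids)
  idx <- which(upper.tri(result$r), arr.ind = TRUE)
  r <- result$r[idx]; p <- result$p[idx]
  keep <- abs(r) > r_threshold & p < p_threshold
  data.frame(taxon_a = result$taxon_ids[idx[keep, 1]],
             taxon_b = result$taxon_ids[idx[keep, 2]],
             r = r[keep], p = p[keep],
             sign = ifelse(r[keep] > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Prepare a count table for network inference
#'
#' Samples under `depth` are removed; taxa found in fewer than
#' `min_prevalence` of the remaining samples are eliminated; the surviving
#' table is subsampled once (seeded) to exactly `depth` reads per sample, so
#' every output row sums to the depth. Samples whose totals fall under depth
#' after the taxon removal are dropped as well.
#'
#' @param table a [taxon_table()].
#' @param depth subsampling depth (2000 for bacterial, 500 for archaeal
#'   communities by convention).
#' @param min_prevalence prevalence cutoff (taxa below are eliminated;
#'   strict `<`).
#' @param seed RNG seed for the subsampling.
#' @return the filtered, subsampled [taxon_table()].
#' @export
prefilter_for_network <- function(table, depth = 2000, min_prevalence = 0.2,
                                  seed = 1) {
  counts <- table$counts[rowSums(table$counts) >= depth, , drop = FALSE]
  keep <- colMeans(counts > 0) >= min_prevalence
  kept <- taxon_table(counts[, keep, drop = FALSE],
                      if (!is.null(table$lineage))
                        table$lineage[colnames(counts)[keep], , drop = FALSE])
  rarefy(kept, depth = depth, iterations = 1, seed = seed)$tables[[1]]
}
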