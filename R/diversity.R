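# Alpha diversity, Bray-Curtis dissimilarity, principal coordinates, and
# permutation PERMANOVA. Indices operate on a single sample's count vector;
# table-level helpers average over rarefaction iterations.

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  counts
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1` singletons and `F2`
#' doubletons.
#'
#' @param counts non-negative integer vector for one sample.
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  if (any(counts != round(counts))) stop("chao1 requires integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `-sum p_i log_base(p_i)` over taxa with positive proportion. Base 2 by
#' default (the convention of the QIIME 1.x alpha-diversity tooling); pass
#' `base = exp(1)` for nats.
#'
#' @param counts non-negative vector for one sample.
#' @param base logarithm base.
#' @export
shannon <- function(counts, base = 2) {
  counts <- check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson diversity index
#'
#' `1 - sum p_i^2` (the probability two reads drawn with replacement come
#' from different taxa).
#'
#' @inheritParams shannon
#' @export
simpson <- function(counts) {
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Good's coverage
#'
#' `1 - F1 / N`: the estimated fraction of the community captured by the
#' sample, with `F1` singleton taxa and `N` total reads.
#'
#' @inheritParams chao1
#' @export
goods_coverage <- function(counts) {
  counts <- check_counts(counts)
  1 - sum(counts == 1) / sum(counts)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; entries in \[0, 1\].
#'
#' @param table a [taxon_table()] or samples x taxa matrix; every sample
#'   total must be positive.
#' @return symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "taxon_table")) table$counts else as.matrix(table)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  as.matrix(vegan::vegdist(counts, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues, and explained fractions are computed over positive
#' eigenvalues only (no Lingoes/Cailliez correction).
#'
#' @param dist symmetric dissimilarity matrix (or `dist` object).
#' @param n_axes number of axes to return; truncated with a warning when the
#'   matrix has fewer positive eigenvalues.
#' @return list with `coordinates` (samples x axes, named `PCoA1..`),
#'   `eigenvalues` (all of them, decreasing), and `explained_fraction` for the
#'   returned axes.
#' @export
pcoa <- function(dist, n_axes = 5) {
  d <- as.matrix(dist)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  # Gower centering
  a <- -0.5 * d^2
  ctr <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  ee <- eigen(ctr, symmetric = TRUE)
  pos <- which(ee$values > max(ee$values) * 1e-12 & ee$values > 0)
  if (length(pos) < n_axes) {
    warning("only ", length(pos), " positive eigenvalues; truncating axes")
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- ee$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ee$values[keep]), n_axes)
  dimnames(coords) <- list(ids, paste0("PCoA", seq_len(n_axes)))
  list(coordinates = coords,
       eigenvalues = ee$values,
       explained_fraction = ee$values[keep] / sum(ee$values[pos]))
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Single-factor pseudo-F test on a dissimilarity matrix (Anderson's method):
#' total and within-group sums of squared distances give
#' `F = ((SS_total - SS_within) / (a - 1)) / (SS_within / (n - a))`, and the
#' raw group labels are permuted to obtain
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + permutations)` — the observed
#' statistic always counts itself, so p is never 0. When `strata` is given,
#' labels are permuted only within strata (e.g. testing a sex effect while
#' constraining permutations within each diet); with strata equal to the
#' groups themselves no permutation can change the labeling and p is 1.
#'
#' @param dist dissimilarity matrix or `dist` object.
#' @param groups factor of group labels (>= 2 distinct groups).
#' @param permutations number of label permutations.
#' @param strata optional blocking factor restricting permutations.
#' @param seed RNG seed for the permutation stream.
#' @return list with `f`, `p`, `r2`, `permutations`.
#' @export
permanova <- function(dist, groups, permutations = 1000, strata = NULL,
                      seed = NULL) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("permanova needs at least 2 groups")
  d2 <- as.matrix(dist)^2
  n <- nrow(d2)
  if (length(groups) != n) stop("groups length does not match the matrix")
  a <- nlevels(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1)
        s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  fstat_of <- function(g) {
    ssw <- ssw_of(g)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- fstat_of(groups)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != n) stop("strata length does not match the matrix")
  }
  perm_labels <- function() {
    if (is.null(strata)) return(groups[sample.int(n)])
    g2 <- groups
    for (s in levels(strata)) {
      ix <- which(strata == s)
      g2[ix] <- groups[ix][sample.int(length(ix))]
    }
    g2
  }
  f_perm <- replicate(permutations, fstat_of(perm_labels()))
  # count ties (degenerate permutations reproduce F exactly) as exceedances
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + permutations)
  ssw <- ssw_of(groups)
  list(f = f_obs, p = p, r2 = (sst - ssw) / sst,
       permutations = permutations)
}

#' Alpha diversity averaged over rarefaction iterations
#'
#' Computes each index on every subsampled table and averages per sample, the
#' conventional aggregation when indices are estimated on counts normalized
#' by repeated subsampling.
#'
#' @param rarefied result of [rarefy()].
#' @param base Shannon base.
#' @return data.frame: sample, chao1, shannon, simpson, goods_coverage.
#' @export
alpha_diversity <- function(rarefied, base = 2) {
  per_iter <- lapply(rarefied$tables, function(tab) {
    cbind(chao1 = apply(tab$counts, 1, chao1),
          shannon = apply(tab$counts, 1, shannon, base = base),
          simpson = apply(tab$counts, 1, simpson),
          goods_coverage = apply(tab$counts, 1, goods_coverage))
  })
  avg <- Reduce(`+`, per_iter) / length(per_iter)
  data.frame(sample = rownames(avg), avg, row.names = NULL,
             stringsAsFactors = FALSE)
}
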