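# Turning raw count tables into analyzable microbial features: rank
# collapsing, detected-taxon filtering, relative abundance, log10 traits with
# outlier removal, and rarefaction.

#' Collapse a count table to a taxonomic rank
#'
#' Counts of taxa sharing the same label at `rank` are summed; per-sample
#' totals are conserved exactly. Taxa unclassified at `rank` are labelled
#' `"unclassified <deepest classified parent>"` so that, e.g., a genus-less
#' member of family F collapses to genus-level taxon `"unclassified F"`.
#'
#' @param table a [taxon_table()] with a lineage.
#' @param rank one of the lineage's column names.
#' @return a [taxon_table()] whose taxa are the labels at `rank`; the new
#'   lineage keeps the ranks down to `rank`.
#' @export
collapse_to_rank <- function(table, rank) {
  if (is.null(table$lineage)) stop("table has no lineage; cannot collapse")
  ranks <- colnames(table$lineage)
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  ri <- match(rank, ranks)
  lin <- table$lineage[colnames(table$counts), , drop = FALSE]
  if (anyNA(rownames(lin)) || nrow(lin) < ncol(table$counts))
    stop("lineage missing for some taxa; cannot collapse")
  labels <- vapply(seq_len(nrow(lin)), function(i) {
    lab <- as.character(lin[i, ri])
    if (!is.na(lab) && nzchar(lab)) return(lab)
    for (j in rev(seq_len(ri - 1))) {
      parent <- as.character(lin[i, j])
      if (!is.na(parent) && nzchar(parent) &&
          !startsWith(parent, "unclassified "))
        return(paste("unclassified", parent))
    }
    "unclassified unknown"
  }, "")
  groups <- factor(labels, levels = unique(labels))
  collapsed <- t(rowsum(t(table$counts), groups))
  colnames(collapsed) <- levels(groups)
  # lineage down to the target rank: take the first member's labels per group
  first <- match(levels(groups), labels)
  new_lin <- lin[first, seq_len(ri), drop = FALSE]
  new_lin[, ri] <- levels(groups)
  rownames(new_lin) <- levels(groups)
  taxon_table(collapsed, new_lin)
}

#' Filter to detected taxa
#'
#' A taxon is "detected" when its maximum per-sample relative abundance
#' exceeds `min_max_relabund` (default 0.5%) in at least one sample AND its
#' prevalence (fraction of samples with a nonzero count) exceeds
#' `min_prevalence` (default 20%). Both inequalities are strict. Idempotent.
#'
#' @param table a [taxon_table()].
#' @param min_max_relabund,min_prevalence detection thresholds.
#' @return the filtered [taxon_table()] (possibly with zero taxa).
#' @export
filter_detected_taxa <- function(table, min_max_relabund = 0.005,
                                 min_prevalence = 0.2) {
  counts <- table$counts
  if (!nrow(counts) || !ncol(counts)) stop("empty count table")
  totals <- rowSums(counts)
  relab <- counts / ifelse(totals > 0, totals, 1)
  keep <- apply(relab, 2, max) > min_max_relabund &
    colMeans(counts > 0) > min_prevalence
  out <- taxon_table(counts[, keep, drop = FALSE],
                     if (!is.null(table$lineage))
                       table$lineage[colnames(counts)[keep], , drop = FALSE])
  out
}

#' Relative abundances
#'
#' @param table a [taxon_table()]; every sample total must be positive.
#' @return samples x taxa matrix of fractions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "))
  table$counts / totals
}

#' log10-transform a feature
#'
#' Positive values map to `log10`; zeros are handled per `zero_policy`:
#' `"missing"` (default) marks them `NA` so the animal model simply has fewer
#' records, `"half-min"` substitutes half the smallest positive value before
#' taking logs. The policy is recorded in the trait's transform log.
#'
#' @param values non-negative numeric vector (named by sample) or
#'   [trait_vector()].
#' @param zero_policy `"missing"` or `"half-min"`.
#' @return a [trait_vector()].
#' @export
log10_trait <- function(values, zero_policy = c("missing", "half-min")) {
  zero_policy <- match.arg(zero_policy)
  v <- as.numeric(values)
  nm <- names(values)
  if (is.null(nm)) nm <- paste0("S", seq_along(v))
  if (any(v < 0, na.rm = TRUE)) stop("log10_trait requires non-negative values")
  out <- rep(NA_real_, length(v))
  pos <- !is.na(v) & v > 0
  out[pos] <- log10(v[pos])
  zero <- !is.na(v) & v == 0
  if (zero_policy == "half-min" && any(zero)) {
    if (!any(pos)) stop("half-min policy undefined: no positive values")
    out[zero] <- log10(min(v[pos]) / 2)
  }
  trait_vector(stats::setNames(out, nm),
               transforms = c(attr(values, "transforms"),
                              list(list(type = "log10",
                                        zero_policy = zero_policy))))
}

#' Remove outliers beyond mean +/- k SD
#'
#' Mean and SD are computed once on the non-missing values; values strictly
#' outside `mean +/- k * sd` are set missing. With zero SD the bounds
#' degenerate to the mean and equal values are all retained. The bounds are
#' recorded in the transform log.
#'
#' @param trait a [trait_vector()] or named numeric with >= 3 non-missing
#'   values.
#' @param k number of standard deviations (default 3).
#' @export
remove_outliers <- function(trait, k = 3) {
  v <- as.numeric(trait)
  nm <- names(trait)
  obs <- !is.na(v)
  if (sum(obs) < 3) stop("need at least 3 non-missing values")
  mu <- mean(v[obs]); sd <- stats::sd(v[obs])
  lo <- mu - k * sd; hi <- mu + k * sd
  out <- v
  out[obs & (v < lo | v > hi)] <- NA_real_
  trait_vector(stats::setNames(out, nm),
               transforms = c(attr(trait, "transforms"),
                              list(list(type = "outlier_removal", k = k,
                                        lower = lo, upper = hi,
                                        n_removed = sum(obs) - sum(!is.na(out))))))
}

#' Rarefy a count table by repeated subsampling
#'
#' Each retained sample is subsampled without replacement to exactly `depth`
#' reads, `iterations` times. Samples whose total is below `depth` are
#' excluded and reported, never partially subsampled.
#'
#' @param table a [taxon_table()].
#' @param depth target depth (>= 1).
#' @param iterations number of independent subsampling iterations.
#' @param seed RNG seed; iteration i uses child seed `seed + i - 1`.
#' @return list with `tables` (list of [taxon_table()]s, one per iteration)
#'   and `excluded` (character vector of under-depth sample ids).
#' @export
rarefy <- function(table, depth, iterations = 100, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(table$counts)
  excluded <- rownames(table$counts)[totals < depth]
  keep <- table$counts[totals >= depth, , drop = FALSE]
  tables <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    set.seed(seed + it - 1)
    # rrarefy heuristically warns whenever the smallest nonzero count
    # exceeds 1; that is expected for collapsed tables, so silence it
    sub <- withCallingHandlers(
      vegan::rrarefy(keep, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    tables[[it]] <- taxon_table(sub, table$lineage)
  }
  list(tables = tables, excluded = excluded, depth = depth, seed = seed)
}
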