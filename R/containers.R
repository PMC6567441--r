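#' Construct a sample-by-taxon count table
#'
#' The root object of the community side of the analysis: an integer count
#' matrix (samples in rows, taxa in columns) with an optional taxonomy lineage
#' table giving, for every taxon, its labels at an ordered set of ranks
#' (e.g. phylum ... genus). Levels without a classification may be `NA`; rank
#' collapsing renders them as `"unclassified <parent>"`.
#'
#' @param counts numeric matrix of non-negative integers; rownames are sample
#'   ids, colnames are taxon ids. Both must be unique.
#' @param lineage optional data.frame of rank labels, one row per taxon
#'   (rownames = taxon ids, columns = ranks ordered coarse to fine).
#' @return an object of class `taxon_table` with elements `counts` and
#'   `lineage`.
#' @export
taxon_table <- function(counts, lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("T", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated taxon ids in count table")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (!is.null(lineage)) {
    lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
    missing_tax <- setdiff(colnames(counts), rownames(lineage))
    if (length(missing_tax))
      warning("no lineage for taxa: ", paste(missing_tax, collapse = ", "))
    lineage <- lineage[intersect(rownames(lineage), colnames(counts)), ,
                       drop = FALSE]
  }
  structure(list(counts = counts, lineage = lineage), class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("taxon_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  if (!is.null(x$lineage))
    cat("  lineage ranks:", paste(colnames(x$lineage), collapse = " > "), "\n")
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Construct a SNP panel
#'
#' Holds a marker map (marker id, chromosome, base-pair position, the two
#' alleles) and an n-samples by m-markers dosage matrix counting copies of
#' allele `a1`, so dosages lie in {0, 1, 2} with `NA` for missing calls.
#'
#' @param dosages numeric matrix, samples x markers; values in {0,1,2,NA};
#'   rownames sample ids, colnames marker ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos`, `a1`, `a2`;
#'   one row per marker, in the column order of `dosages`. `chrom`/`pos` may
#'   be `NA` for markers without a known position (kept in the relationship
#'   matrix but excluded from association scans).
#' @return object of class `snp_panel`.
#' @export
snp_panel <- function(dosages, map) {
  dosages <- as.matrix(dosages)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  if (is.null(colnames(dosages))) colnames(dosages) <- map$marker
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("A", seq_len(nrow(dosages)))
  if (anyDuplicated(map$marker)) stop("duplicated marker ids in map")
  if (!identical(colnames(dosages), as.character(map$marker)))
    stop("dosage columns do not match map markers")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2, or NA")
  # positions must be non-decreasing within each chromosome
  for (ch in unique(map$chrom[!is.na(map$chrom)])) {
    p <- map$pos[!is.na(map$chrom) & map$chrom == ch]
    if (any(is.na(p)) || is.unsorted(p))
      stop("positions not non-decreasing on chromosome ", ch)
  }
  structure(list(dosages = dosages, map = map), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", nrow(x$dosages), "samples x", nrow(x$map), "markers")
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf(" (%.2f%% missing)\n", 100 * nmiss / length(x$dosages)))
  invisible(x)
}

#' Construct a trait vector
#'
#' One analyzable feature per sample (a log10 relative abundance, an alpha
#' diversity index, a principal-coordinate score, a host phenotype, ...),
#' carrying an ordered record of the transforms that produced it.
#'
#' @param values named numeric vector (names = sample ids); `NA` marks missing
#'   records.
#' @param transforms list describing applied transforms, appended to by
#'   [log10_trait()], [remove_outliers()], [adjust_phenotype()] etc.
#' @export
trait_vector <- function(values, transforms = list()) {
  values <- unlist(values)
  if (is.null(names(values))) stop("trait values must be named by sample id")
  if (anyDuplicated(names(values))) stop("duplicated sample ids in trait")
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values),
            transforms = transforms, class = "trait_vector")
}

#' @export
print.trait_vector <- function(x, ...) {
  cat("trait_vector:", length(x), "samples,", sum(is.na(x)), "missing\n")
  tr <- attr(x, "transforms")
  if (length(tr)) cat("  transforms:",
                      paste(vapply(tr, function(t) t$type, ""), collapse = " -> "),
                      "\n")
  invisible(x)
}

# append a transform record, preserving class/attributes
add_transform <- function(trait, record) {
  tr <- c(attr(trait, "transforms"), list(record))
  attr(trait, "transforms") <- tr
  trait
}

#' Genomic relationship matrix container
#'
#' @param g symmetric n x n matrix with sample ids as dimnames.
#' @param n_markers_used number of markers entering the construction.
#' @param allele_freqs per-marker allele frequencies used for centering.
#' @seealso [build_grm()]
#' @export
grm <- function(g, n_markers_used = NA_integer_, allele_freqs = NULL) {
  g <- as.matrix(g)
  if (nrow(g) != ncol(g)) stop("grm must be square")
  if (is.null(rownames(g))) rownames(g) <- colnames(g) <- paste0("A", seq_len(nrow(g)))
  if (max(abs(g - t(g))) > 1e-10) stop("grm must be symmetric within 1e-10")
  g <- (g + t(g)) / 2
  structure(list(g = g, sample_ids = rownames(g),
                 n_markers_used = n_markers_used,
                 allele_freqs = allele_freqs),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$g), "x", ncol(x$g),
      "| markers used:", x$n_markers_used,
      "| mean diag:", round(mean(diag(x$g)), 3), "\n")
  invisible(x)
}
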