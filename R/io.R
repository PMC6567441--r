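# Plain-text readers and writers. TSV is the lingua franca; writers prepend a
# single '#' comment line with package version, seed, and a parameter digest
# so every output is traceable to the run that produced it.

provenance_header <- function(seed = NA, params = list()) {
  digest <- if (length(params)) {
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","), ""),
          sep = "=", collapse = ";")
  } else ""
  sprintf("# microherit %s | seed=%s | %s",
          as.character(utils::packageVersion("microherit")),
          format(seed), digest)
}

write_tsv <- function(df, path, seed = NA, params = list(), row_col = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, params), con)
  if (!is.null(row_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                row_col), df)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a sample-by-taxon count table from TSV
#'
#' Expects a header row of taxon ids and a first column of sample ids. An
#' optional lineage TSV (first column taxon id, one column per rank) is joined
#' onto the table. Lines starting with `#` are ignored.
#'
#' @param path count table TSV.
#' @param lineage_path optional lineage TSV.
#' @return a [taxon_table()].
#' @export
read_count_table <- function(path, lineage_path = NULL) {
  df <- read_tsv(path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("count table contains negative, fractional, or missing values")
  lineage <- NULL
  if (!is.null(lineage_path)) {
    ldf <- read_tsv(lineage_path)
    lineage <- ldf[, -1, drop = FALSE]
    rownames(lineage) <- as.character(ldf[[1]])
  }
  taxon_table(counts, lineage)
}

#' Write a count table (and its lineage) as TSV
#'
#' @param table a [taxon_table()].
#' @param path output TSV path; the lineage (if any) goes to
#'   `<path base>.lineage.tsv`.
#' @param seed,params recorded in the provenance header line.
#' @export
write_count_table <- function(table, path, seed = NA, params = list()) {
  df <- as.data.frame(table$counts, check.names = FALSE)
  write_tsv(df, path, seed = seed, params = params, row_col = "sample")
  if (!is.null(table$lineage)) {
    lpath <- sub("\\.tsv$", "", path)
    write_tsv(table$lineage, paste0(lpath, ".lineage.tsv"),
              seed = seed, row_col = "taxon")
  }
  invisible(path)
}

#' Read a genotype panel
#'
#' Two dialects are supported:
#' \describe{
#' \item{`"plink-text"`}{`<prefix>.ped` / `<prefix>.map` pair. The `.ped`
#'   carries family/individual ids, parental ids, sex and phenotype followed
#'   by two allele calls per marker (`0 0` = missing); the `.map` carries
#'   chromosome, marker id, genetic distance, and base-pair position. Dosage
#'   counts copies of the marker's first-seen allele.}
#' \item{`"dosage-tsv"`}{a samples x markers dosage TSV (values 0/1/2, blank
#'   or NA = missing) plus a marker map TSV with columns marker, chrom, pos,
#'   a1, a2 at `<prefix>.map.tsv`.}
#' }
#'
#' @param prefix path prefix (without extension).
#' @param dialect `"plink-text"` or `"dosage-tsv"`.
#' @return a [snp_panel()].
#' @export
read_genotypes <- function(prefix, dialect = c("plink-text", "dosage-tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink-text") {
    map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "marker", "cm", "pos"))
    ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    m <- nrow(map)
    if (ncol(ped) != 6 + 2 * m)
      stop("malformed .ped: expected ", 6 + 2 * m, " fields, found ", ncol(ped))
    ids <- ped[[2]]
    a_first <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
    a_second <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
    dos <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, map$marker))
    a1 <- a2 <- character(m)
    for (j in seq_len(m)) {
      obs <- c(a_first[, j], a_second[, j])
      alleles <- setdiff(unique(obs), "0")
      if (length(alleles) > 2)
        stop("marker ", map$marker[j], " has more than two alleles")
      a1[j] <- if (length(alleles) >= 1) alleles[1] else "0"
      a2[j] <- if (length(alleles) == 2) alleles[2] else a1[j]
      miss <- a_first[, j] == "0" | a_second[, j] == "0"
      dos[, j] <- (a_first[, j] == a1[j]) + (a_second[, j] == a1[j])
      dos[miss, j] <- NA_real_
    }
    map_out <- data.frame(marker = map$marker, chrom = map$chrom,
                          pos = map$pos, a1 = a1, a2 = a2,
                          stringsAsFactors = FALSE)
    snp_panel(dos, map_out)
  } else {
    ddf <- read_tsv(paste0(prefix, ".dosage.tsv"))
    dos <- as.matrix(ddf[, -1, drop = FALSE])
    rownames(dos) <- as.character(ddf[[1]])
    bad <- dos[!is.na(dos)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      stop("dosage file contains values outside {0,1,2,NA}")
    map <- read_tsv(paste0(prefix, ".map.tsv"))
    snp_panel(dos, map)
  }
}

#' Write a genotype panel
#'
#' @param panel a [snp_panel()].
#' @param prefix output path prefix.
#' @param dialect `"plink-text"` or `"dosage-tsv"` (see [read_genotypes()]).
#' @param seed,params provenance for TSV headers (ignored for plink-text,
#'   which has no comment syntax).
#' @export
write_genotypes <- function(panel, prefix, dialect = c("plink-text", "dosage-tsv"),
                            seed = NA, params = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "plink-text") {
    map <- panel$map
    utils::write.table(
      data.frame(map$chrom, map$marker, 0, map$pos),
      paste0(prefix, ".map"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    n <- nrow(panel$dosages); m <- nrow(map)
    out <- matrix("0", n, 2 * m)
    for (j in seq_len(m)) {
      d <- panel$dosages[, j]
      out[, 2 * j - 1] <- ifelse(is.na(d), "0", ifelse(d >= 1, map$a1[j], map$a2[j]))
      out[, 2 * j]     <- ifelse(is.na(d), "0", ifelse(d == 2, map$a1[j], map$a2[j]))
    }
    ped <- cbind(rownames(panel$dosages), rownames(panel$dosages),
                 "0", "0", "0", "-9", out)
    utils::write.table(ped, paste0(prefix, ".ped"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    write_tsv(as.data.frame(panel$dosages, check.names = FALSE),
              paste0(prefix, ".dosage.tsv"), seed = seed, params = params,
              row_col = "sample")
    write_tsv(panel$map, paste0(prefix, ".map.tsv"), seed = seed)
  }
  invisible(prefix)
}

#' Write a genomic relationship matrix
#'
#' Emits both the full square matrix and a three-column sparse
#' lower-triangle form (`id_i`, `id_j`, `g`).
#'
#' @param x a [grm()].
#' @param path output path for the square TSV; the sparse form goes to
#'   `<path base>.sparse.tsv`.
#' @param seed,params provenance header fields.
#' @export
write_grm <- function(x, path, seed = NA, params = list()) {
  write_tsv(as.data.frame(x$g, check.names = FALSE), path,
            seed = seed, params = params, row_col = "sample")
  idx <- which(lower.tri(x$g, diag = TRUE), arr.ind = TRUE)
  sp <- data.frame(id_i = rownames(x$g)[idx[, 1]],
                   id_j = colnames(x$g)[idx[, 2]],
                   g = x$g[idx])
  write_tsv(sp, paste0(sub("\\.tsv$", "", path), ".sparse.tsv"), seed = seed)
  invisible(path)
}
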