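# The end-to-end driver: filter -> rarefy -> diversity/PCoA -> traits ->
# SNP QC -> GRM -> heritability per feature -> GWAS on eligible features ->
# SparCC network -> correlation screen, with per-stage bookkeeping in a run
# manifest. Every stochastic stage consumes a child seed derived from the
# global seed so reruns are bit-reproducible.

#' Assemble and validate a pipeline configuration
#'
#' @param counts path to the count table TSV.
#' @param metadata path to the per-sample metadata TSV (columns `sample`,
#'   the fixed-effect factors/covariates, and any host traits to screen).
#' @param genotypes path prefix for the genotype panel.
#' @param out_dir output directory (created if absent).
#' @param lineage optional lineage TSV.
#' @param genotype_dialect `"dosage-tsv"` or `"plink-text"`.
#' @param rank rank to collapse to (`NULL` = use the table as-is).
#' @param min_max_relabund,min_prevalence detected-taxon thresholds.
#' @param depth,rarefaction_iterations rarefaction settings.
#' @param shannon_base Shannon logarithm base.
#' @param n_pcoa_axes principal-coordinate axes kept as traits.
#' @param permanova_permutations label permutations per factor test.
#' @param hwe_p_min,maf_min,callrate_min SNP QC thresholds.
#' @param h2_heritable,h2_gwas heritable / GWAS-eligibility cutoffs.
#' @param fdr_significant,fdr_suggestive association tiers.
#' @param sparcc_permutations,sparcc_inner_iterations,sparcc_perm_inner_iterations
#'   network inference settings.
#' @param r_threshold,p_threshold network edge filter.
#' @param screen_traits host trait columns for the correlation screen
#'   (missing columns are skipped; FCR/RFI/RFIf are derived when DMI, ADG,
#'   MWT and backfat are available).
#' @param formula fixed-effects formula.
#' @param seed global seed.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(counts, metadata, genotypes, out_dir,
                       lineage = NULL, genotype_dialect = "dosage-tsv",
                       rank = NULL,
                       min_max_relabund = 0.005, min_prevalence = 0.2,
                       depth = 2000, rarefaction_iterations = 100,
                       shannon_base = 2, n_pcoa_axes = 5,
                       permanova_permutations = 1000,
                       hwe_p_min = 1e-6, maf_min = 0.05, callrate_min = 0.90,
                       h2_heritable = 0.15, h2_gwas = 0.1,
                       fdr_significant = 0.1, fdr_suggestive = 0.2,
                       sparcc_permutations = 10000,
                       sparcc_inner_iterations = 20,
                       sparcc_perm_inner_iterations = 5,
                       r_threshold = 0.3, p_threshold = 0.001,
                       screen_traits = c("DMI", "ADG", "FCR", "RFI", "RFIf",
                                         "acetate", "propionate", "butyrate"),
                       formula = ~ breed + sex + diet + age,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(depth >= 1, rarefaction_iterations >= 1,
            permanova_permutations >= 1, sparcc_permutations >= 1)
  for (thr in c("min_max_relabund", "min_prevalence", "maf_min",
                "callrate_min", "h2_heritable", "h2_gwas",
                "fdr_significant", "fdr_suggestive", "p_threshold")) {
    v <- cfg[[thr]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config threshold out of [0, 1]: ", thr, " = ", v)
  }
  if (r_threshold < 0 || r_threshold > 1) stop("r_threshold out of [0, 1]")
  class(cfg) <- "run_config"
  cfg
}

# deterministic child seed per stage
child_seed <- function(seed, stage_index) seed * 1000L + stage_index

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writes each stage's outputs as headed TSVs
#' under `config$out_dir`, and returns a run manifest recording, per stage,
#' the parameters, row/column bookkeeping, output files and their md5 hashes.
#' Any stage failure aborts with the stage name and leaves a `FAILED` marker
#' file next to the partial outputs.
#'
#' @param config a [run_config()].
#' @return the manifest (class `run_manifest`), invisibly also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  stage_i <- 0L
  outputs <- character()
  t0 <- proc.time()[["elapsed"]]
  current_stage <- "init"

  note <- function(stage, params, info, files) {
    manifest[[stage]] <<- list(stage = stage, params = params, info = info,
                               files = files)
    outputs <<- c(outputs, files)
  }
  run_stage <- function(stage, expr) {
    current_stage <<- stage
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sd <- function() child_seed(config$seed, stage_i)
  path <- function(f) file.path(config$out_dir, f)

  # -- inputs ---------------------------------------------------------------
  stage_i <- 1L
  tab <- run_stage("read_inputs", {
    read_count_table(config$counts, config$lineage)
  })
  md <- read_tsv(config$metadata)
  panel <- read_genotypes(config$genotypes, config$genotype_dialect)
  note("read_inputs",
       list(counts = config$counts, metadata = config$metadata,
            genotypes = config$genotypes),
       list(n_samples = nrow(tab$counts), n_taxa = ncol(tab$counts),
            n_markers = nrow(panel$map), n_metadata_rows = nrow(md)),
       character())

  # -- features -------------------------------------------------------------
  stage_i <- 2L
  detected <- run_stage("features", {
    t2 <- if (!is.null(config$rank)) collapse_to_rank(tab, config$rank) else tab
    filter_detected_taxa(t2, config$min_max_relabund, config$min_prevalence)
  })
  f_detected <- path("detected_taxa.tsv")
  write_count_table(detected, f_detected, seed = config$seed,
                    params = list(rank = config$rank %||% "as-is",
                                  min_max_relabund = config$min_max_relabund,
                                  min_prevalence = config$min_prevalence))
  note("features", config[c("rank", "min_max_relabund", "min_prevalence")],
       list(n_taxa_in = ncol(tab$counts), n_taxa_detected = ncol(detected$counts)),
       f_detected)

  # -- diversity ------------------------------------------------------------
  stage_i <- 3L
  rar <- run_stage("diversity", rarefy(detected, config$depth,
                                       config$rarefaction_iterations,
                                       seed = sd()))
  alpha <- alpha_diversity(rar, base = config$shannon_base)
  f_alpha <- path("alpha_diversity.tsv")
  write_tsv(alpha, f_alpha, seed = sd(),
            params = list(depth = config$depth,
                          iterations = config$rarefaction_iterations))
  # PCoA on a single seeded rarefaction (the first iteration)
  bc <- bray_curtis(rar$tables[[1]])
  pc <- pcoa(bc, n_axes = config$n_pcoa_axes)
  f_pcoa <- path("pcoa.tsv")
  pcd <- data.frame(sample = rownames(pc$coordinates), pc$coordinates,
                    row.names = NULL, check.names = FALSE)
  write_tsv(pcd, f_pcoa, seed = sd(),
            params = list(explained = round(pc$explained_fraction, 4)))
  # PERMANOVA per factor
  fac_vars <- all.vars(config$formula)
  md_idx <- match(rownames(bc), as.character(md$sample))
  perm_rows <- list()
  for (v in fac_vars) {
    if (!v %in% names(md)) next
    g <- md[[v]][md_idx]
    if (is.numeric(g) || length(unique(stats::na.omit(g))) < 2) next
    ok <- !is.na(g)
    pv <- permanova(bc[ok, ok], g[ok],
                    permutations = config$permanova_permutations,
                    seed = sd() + match(v, fac_vars))
    perm_rows[[v]] <- data.frame(factor = v, f = pv$f, r2 = pv$r2, p = pv$p)
  }
  f_perm <- path("permanova.tsv")
  write_tsv(do.call(rbind, perm_rows), f_perm, seed = sd(),
            params = list(permutations = config$permanova_permutations))
  note("diversity",
       config[c("depth", "rarefaction_iterations", "permanova_permutations")],
       list(n_excluded_samples = length(rar$excluded)),
       c(f_alpha, f_pcoa, f_perm))

  # -- microbial trait matrix ----------------------------------------------
  stage_i <- 4L
  feats <- run_stage("traits", {
    relab <- relative_abundance(detected)
    cols <- lapply(colnames(relab), function(tx)
      remove_outliers(log10_trait(stats::setNames(relab[, tx],
                                                  rownames(relab)))))
    names(cols) <- colnames(relab)
    ids <- rownames(relab)
    mat <- sapply(cols, function(tr) as.numeric(tr[ids]))
    rownames(mat) <- ids
    # alpha indices and PCoA axes as traits, outlier-screened the same way
    amat <- as.matrix(alpha[, c("chao1", "shannon", "simpson")])
    rownames(amat) <- alpha$sample
    for (cn in colnames(amat)) {
      tr <- remove_outliers(stats::setNames(amat[, cn], rownames(amat)))
      v <- rep(NA_real_, length(ids)); names(v) <- ids
      v[names(tr)] <- as.numeric(tr)
      mat <- cbind(mat, stats::setNames(data.frame(v), cn))
    }
    for (cn in colnames(pc$coordinates)) {
      tr <- remove_outliers(stats::setNames(pc$coordinates[, cn],
                                            rownames(pc$coordinates)))
      v <- rep(NA_real_, length(ids)); names(v) <- ids
      v[names(tr)] <- as.numeric(tr)
      mat <- cbind(mat, stats::setNames(data.frame(v), cn))
    }
    as.matrix(mat)
  })
  f_traits <- path("microbial_traits.tsv")
  write_tsv(as.data.frame(feats, check.names = FALSE), f_traits,
            seed = config$seed, params = list(transform = "log10+outlier3SD"),
            row_col = "sample")
  note("traits", list(transform = "log10 (zeros missing), outliers 3SD"),
       list(n_features = ncol(feats)), f_traits)

  # -- genotype QC and GRM --------------------------------------------------
  stage_i <- 5L
  qc <- run_stage("genoqc", qc_snps(panel, config$hwe_p_min, config$maf_min,
                                    config$callrate_min))
  imp <- impute_missing(qc$panel, method = "mean")
  G <- build_grm(imp)
  f_qc <- path("snp_qc_report.tsv")
  write_tsv(qc$report, f_qc, seed = config$seed,
            params = config[c("hwe_p_min", "maf_min", "callrate_min")])
  f_grm <- path("grm.tsv")
  write_grm(G, f_grm, seed = config$seed)
  note("genoqc", config[c("hwe_p_min", "maf_min", "callrate_min")],
       list(n_markers_in = qc$n_input, n_markers_retained = qc$n_retained),
       c(f_qc, f_grm))

  # -- heritability ---------------------------------------------------------
  stage_i <- 6L
  design <- run_stage("heritability", build_design(md, config$formula))
  h2tab <- heritability_screen(feats, design, G,
                               threshold = config$h2_heritable)
  f_h2 <- path("heritability.tsv")
  write_tsv(h2tab, f_h2, seed = config$seed,
            params = list(formula = deparse(config$formula),
                          threshold = config$h2_heritable))
  note("heritability", list(formula = deparse(config$formula)),
       list(n_features = nrow(h2tab),
            n_heritable = sum(h2tab$heritable, na.rm = TRUE)),
       f_h2)

  # -- GWAS -----------------------------------------------------------------
  stage_i <- 7L
  gwas_tab <- run_stage("gwas", {
    eligible <- h2tab$feature[!is.na(h2tab$h2) & h2tab$converged &
                                h2tab$h2 >= config$h2_gwas]
    rows <- list()
    for (f in eligible) {
      tr <- stats::setNames(feats[, f], rownames(feats))
      adj <- adjust_phenotype(tr, design)
      scan <- mixed_model_scan(adj, imp, G)
      hits <- scan[scan$tier != "none", , drop = FALSE]
      if (nrow(hits)) {
        hits$feature <- f
        rows[[f]] <- hits
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(marker = character(), chrom = integer(), pos = integer(),
                 beta = numeric(), se_beta = numeric(), p_value = numeric(),
                 monomorphic = logical(), fdr = numeric(), tier = character(),
                 feature = character())
  })
  f_gwas <- path("associations.tsv")
  write_tsv(as.data.frame(gwas_tab), f_gwas, seed = config$seed,
            params = config[c("h2_gwas", "fdr_significant", "fdr_suggestive")])
  note("gwas", config[c("h2_gwas", "fdr_significant", "fdr_suggestive")],
       list(n_records = nrow(gwas_tab)), f_gwas)

  # -- SparCC network -------------------------------------------------------
  stage_i <- 8L
  net <- run_stage("network", {
    nettab <- prefilter_for_network(detected, depth = config$depth,
                                    min_prevalence = config$min_prevalence,
                                    seed = sd())
    if (ncol(nettab$counts) < 10) {
      list(edges = data.frame(), n_taxa = ncol(nettab$counts))
    } else {
      sp <- sparcc_correlations(nettab,
                                inner_iterations = config$sparcc_inner_iterations,
                                seed = sd())
      sp <- sparcc_pvalues(nettab, sp,
                           permutations = config$sparcc_permutations,
                           seed = sd(),
                           inner_iterations = config$sparcc_perm_inner_iterations)
      list(edges = build_network(sp, config$r_threshold, config$p_threshold),
           n_taxa = ncol(nettab$counts))
    }
  })
  f_net <- path("network_edges.tsv")
  write_tsv(net$edges, f_net, seed = sd(),
            params = config[c("sparcc_permutations", "r_threshold",
                              "p_threshold")])
  note("network", config[c("sparcc_permutations", "r_threshold", "p_threshold")],
       list(n_taxa = net$n_taxa, n_edges = nrow(net$edges)), f_net)

  # -- correlation screen ---------------------------------------------------
  stage_i <- 9L
  screen <- run_stage("screen", {
    heritable <- select_heritable_features(h2tab, config$h2_heritable)
    host <- md
    if (all(c("DMI", "ADG") %in% names(host)) && !"FCR" %in% names(host))
      host$FCR <- compute_fcr(host$DMI, host$ADG)
    if (all(c("DMI", "ADG", "MWT") %in% names(host)) &&
        !"RFI" %in% names(host)) {
      rfi <- compute_rfi(host$DMI, host$ADG, host$MWT,
                         backfat = if ("backfat" %in% names(host))
                           host$backfat)
      host$RFI <- rfi$rfi
      if (!is.null(rfi$rfif)) host$RFIf <- rfi$rfif
    }
    tcols <- intersect(config$screen_traits, names(host))
    if (!length(heritable) || !length(tcols)) return(NULL)
    tmat <- as.matrix(host[, tcols, drop = FALSE])
    rownames(tmat) <- as.character(host$sample)
    spearman_screen(feats[, heritable, drop = FALSE], tmat)
  })
  f_screen <- path("correlation_screen.tsv")
  empty_screen <- data.frame(feature = character(), trait = character(),
                             rho = numeric(), p = numeric(), n = numeric(),
                             significant = logical())
  write_tsv(if (is.null(screen)) empty_screen else screen$long, f_screen,
            seed = config$seed, params = list(p_threshold = 0.05))
  note("screen", list(p_threshold = 0.05),
       list(n_pairs = if (is.null(screen)) 0L else nrow(screen$long)),
       f_screen)

  # -- manifest -------------------------------------------------------------
  hashes <- tools::md5sum(outputs)
  rows <- do.call(rbind, lapply(manifest, function(st) {
    files <- if (length(st$files)) st$files else NA_character_
    data.frame(stage = st$stage,
               params = paste(names(st$params),
                              vapply(st$params, function(p)
                                paste(format(p), collapse = ","), ""),
                              sep = "=", collapse = ";"),
               info = paste(names(st$info),
                            vapply(st$info, function(p)
                              paste(format(p), collapse = ","), ""),
                            sep = "=", collapse = ";"),
               files = paste(basename(files), collapse = ","),
               md5 = paste(unname(hashes[files]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path("manifest.tsv"), seed = config$seed,
            params = list(version = as.character(utils::packageVersion("microherit"))))
  res <- structure(list(stages = manifest, table = rows,
                        out_dir = config$out_dir, seed = config$seed,
                        wall_clock = proc.time()[["elapsed"]] - t0),
                   class = "run_manifest")
  invisible(res)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$stages), "stages in", x$out_dir,
      sprintf("(%.1f s)\n", x$wall_clock))
  for (st in x$stages)
    cat(" -", st$stage, "|",
        paste(names(st$info), unlist(st$info), sep = "=", collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
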