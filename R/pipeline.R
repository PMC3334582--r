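#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: either file inputs
#' (VCF + map + phenotypes) or simulation specs, the population role
#' mapping, and the analysis thresholds with their conventional
#' defaults (95% call rates, r^2 0.5 pruning, pi-hat 0.25 exclusion,
#' 5% MAF, top 0.1% outliers, 100 kb gene flank, 0.005 cM / 5 kb
#' windows, Ne 15700).
#'
#' @param out_dir output directory.
#' @param seed global integer seed; per-stage seeds are derived from it
#'   by a fixed affine hash so stages can be re-run alone.
#' @param bn_spec a [bn_sim_spec()] for the genome-wide genotypes.
#' @param sweep_spec a [sweep_sim_spec()] for the swept region.
#' @param pheno_spec a [pheno_sim_spec()].
#' @param vcf,map_file,pheno_file optional file inputs replacing the
#'   simulation (exactly one route must be chosen).
#' @param thresholds named list overriding any default threshold.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       bn_spec = bn_sim_spec(),
                       sweep_spec = sweep_sim_spec(chrom = "2"),
                       pheno_spec = pheno_sim_spec(),
                       vcf = NULL, map_file = NULL, pheno_file = NULL,
                       thresholds = list()) {
  th <- list(snp_call_min = 0.95, sample_call_min = 0.95,
             r2_prune = 0.5, pihat_max = 0.25, maf_min = 0.05,
             outlier_fraction = 0.001, flank_bp = 1e5,
             window_cm = 0.005, step_bp = 5000, Ne = 15700,
             causal_effect = 0)
  th[names(thresholds)] <- thresholds
  stopifnot(th$outlier_fraction >= 0, th$outlier_fraction < 1,
            th$r2_prune > 0, th$r2_prune <= 1)
  simulate <- is.null(vcf)
  if (!simulate && (is.null(map_file) || is.null(pheno_file)))
    stop("file-input route needs vcf, map_file and pheno_file")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate,
                 bn_spec = bn_spec, sweep_spec = sweep_spec,
                 pheno_spec = pheno_spec,
                 vcf = vcf, map_file = map_file,
                 pheno_file = pheno_file, thresholds = th),
            class = "run_config")
}

# fixed per-stage seed derivation (stage-level reproducibility)
.stage_seed <- function(seed, stage) {
  (as.double(seed) * 1000003 + stage * 7919) %% 2147483647
}

#' Run the full scan-and-associate pipeline
#'
#' Executes, in dependency order: data acquisition (simulation or file
#' input), genotype QC, relatedness exclusion, LD pruning and PCA,
#' F_ST and LSBL scans with empirical outlier calling, the iHS scan on
#' the swept region, the XP-CLR window scan, core-haplotype
#' frequencies, gene-window enrichment, the hemoglobin group test and
#' the mixed-model association.  All tables are written as TSV under
#' `config$out_dir`; the returned manifest records per-stage counts and
#' output paths and is written as JSON.
#'
#' @param config a [run_config()].
#' @return The manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(seed = config$seed, stages = list(), outputs = list())
  out <- function(name) file.path(config$out_dir, name)

  ## stage 1: data
  if (config$simulate) {
    bn <- simulate_bn_genotypes(config$bn_spec,
                                seed = .stage_seed(config$seed, 1))
    sweep <- simulate_sweep_haplotypes(config$sweep_spec,
                                       seed = .stage_seed(config$seed, 2))
    gm <- bn$gm
  } else {
    gm <- read_vcf(config$vcf)
    ph_in <- read_phenotypes(config$pheno_file)
    gm$samples$population <- ph_in$population[match(gm$samples$id,
                                                    ph_in$sample)]
    bn <- list(gm = gm, truth = data.frame(snp_id = character(0)))
    sweep <- NULL
  }
  manifest$stages$data <- list(n_samples = nrow(gm$samples),
                               n_snps = nrow(gm$snps))

  ## stage 2: QC
  gm <- qc_filter(gm, th$snp_call_min, th$sample_call_min)
  manifest$stages$qc <- list(
    snps_removed = length(attr(gm, "snps_removed")),
    samples_removed = length(attr(gm, "samples_removed")),
    n_snps = nrow(gm$snps), n_samples = nrow(gm$samples))

  ## stage 3: relatedness + structure
  rel <- pihat(gm)
  drop_ids <- exclude_related(rel, th$pihat_max)
  if (length(drop_ids) > 0)
    gm <- gm_subset(gm, samples = setdiff(gm$samples$id, drop_ids))
  pruned_ids <- ld_prune(gm, r2_max = th$r2_prune)
  pc <- pca(gm_subset(gm, snps = pruned_ids), n_components = 5)
  pc_df <- data.frame(sample = rownames(pc$coordinates),
                      population = gm$samples$population,
                      pc$coordinates)
  utils::write.table(pc_df, out("pca.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$stages$structure <- list(
    related_removed = length(drop_ids),
    n_pruned = length(pruned_ids),
    pc1_var = pc$variance_fraction[1], pc2_var = pc$variance_fraction[2])
  manifest$outputs$pca <- out("pca.tsv")

  ## stage 4: F_ST and LSBL scans
  fst <- wc_fst_scan(gm, "A", "B")
  fst_tab <- score_table(gm$snps$id, gm$snps$chrom, gm$snps$pos,
                         "FST", fst)
  write_score_table(fst_tab, out("fst.tsv"))
  d <- pairwise_distances(gm, c("A", "B", "C"))
  lsbl_tab <- score_table(d$snp_id, d$chrom, d$pos, "LSBL", lsbl(d, "A"))
  write_score_table(lsbl_tab, out("lsbl.tsv"))
  fst_top <- empirical_top(fst_tab, th$outlier_fraction)
  lsbl_top <- empirical_top(lsbl_tab, th$outlier_fraction)
  manifest$stages$freq_scans <- list(
    fst_threshold = fst_top$threshold, n_fst_outliers =
      length(fst_top$outliers),
    lsbl_threshold = lsbl_top$threshold, n_lsbl_outliers =
      length(lsbl_top$outliers))
  manifest$outputs$fst <- out("fst.tsv")
  manifest$outputs$lsbl <- out("lsbl.tsv")

  ## stage 5: haplotype scans on the swept region
  ihs_top <- list(threshold = NA, outliers = character(0))
  if (!is.null(sweep)) {
    hm_A <- hm_subset_pop(sweep$hm, "A")
    hm_A <- maf_filter(hm_A, th$maf_min)
    scan <- ihs_scan(hm_A)
    std <- ihs_standardize(scan$raw, scan$derived_freq)
    ihs_tab <- score_table(scan$snp_id, scan$chrom, scan$pos, "IHS",
                           std$ihs)
    write_score_table(ihs_tab, out("ihs.tsv"))
    ihs_top <- empirical_top(ihs_tab, th$outlier_fraction,
                             use_absolute = TRUE)
    core_idx <- sweep$truth$focal_index + (-1:1)
    core <- core_haplotype_freq(sweep$hm, core_idx)
    utils::write.table(core, out("core_haplotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    xp <- xpclr_scan(hm_subset_pop(sweep$hm, "A"),
                     hm_subset_pop(sweep$hm, "B"), sweep$map,
                     window_cm = th$window_cm, step_bp = th$step_bp)
    xp_tab <- score_table(sprintf("win%04d", seq_len(nrow(xp))),
                          xp$chrom, xp$mid_bp, "XPCLR", xp$score)
    write_score_table(xp_tab, out("xpclr.tsv"))
    xp_top <- empirical_top(xp_tab, max(th$outlier_fraction, 1e-3))
    manifest$stages$hap_scans <- list(
      n_ihs_defined = sum(!is.na(std$ihs)),
      ihs_threshold = ihs_top$threshold,
      n_xpclr_windows = nrow(xp),
      top_xpclr_mid_bp = xp$mid_bp[which.max(xp$score)])
    manifest$outputs$ihs <- out("ihs.tsv")
    manifest$outputs$xpclr <- out("xpclr.tsv")
    manifest$outputs$core_haplotypes <- out("core_haplotypes.tsv")
  }

  ## stage 6: enrichment (synthetic tiled gene annotation when none given)
  genes <- .tiled_genes(gm$snps)
  lsbl_snps <- gm$snps[gm$snps$id %in% lsbl_top$outliers, , drop = FALSE]
  cand <- genes_near_snps(lsbl_snps, genes, th$flank_bp)
  backg <- genes_near_snps(gm$snps, genes, th$flank_bp)
  enr <- NULL
  if (length(cand) > 0) {
    sets <- .demo_gene_sets(backg, seed = .stage_seed(config$seed, 6))
    enr <- gene_set_chisq(cand, backg, sets)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$outputs$enrichment <- out("enrichment.tsv")
  }
  fst_snps <- gm$snps[gm$snps$id %in% fst_top$outliers, , drop = FALSE]
  inter <- scan_intersection(list(
    FST = genes_near_snps(fst_snps, genes, th$flank_bp),
    LSBL = cand))
  manifest$stages$enrichment <- list(
    n_candidate_genes = length(cand), n_background_genes = length(backg),
    n_intersection = length(inter$intersection))

  ## stage 7: association
  assoc_gm <- gm_subset(gm, samples = gm$samples$population %in%
                          c("A", "B"))
  K <- ibs_kinship(assoc_gm)
  pheno <- simulate_phenotypes(
    assoc_gm, K = unclass(K), spec = config$pheno_spec,
    seed = .stage_seed(config$seed, 7))$phenotypes
  write_phenotypes(pheno, out("phenotypes.tsv"))
  kw <- kruskal_wallis(pheno$hemoglobin_gdl, pheno$population)
  X <- cbind(1, pheno$age, pheno$altitude_m)
  null <- lmm_fit_null(pheno$hemoglobin_gdl, X, K)
  subset_idx <- .flank_snps(assoc_gm$snps, lsbl_snps, th$flank_bp)
  manifest$stages$association <- list(
    kruskal_H = kw$H, kruskal_p = kw$p,
    pseudo_heritability = null$pseudo_heritability,
    n_snps_tested = length(subset_idx))
  if (length(subset_idx) > 0) {
    assoc <- lmm_snp_assoc(assoc_gm, subset_idx, null)
    utils::write.table(assoc, out("assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$outputs$assoc <- out("assoc.tsv")
  }
  manifest$outputs$phenotypes <- out("phenotypes.tsv")

  manifest$outlier_ids <- list(FST = fst_top$outliers,
                               LSBL = lsbl_top$outliers,
                               IHS = ihs_top$outliers)
  manifest$truth <- list(planted_outliers = bn$truth$snp_id,
                         focal_snp = if (!is.null(sweep))
                           sweep$truth$focal_snp else NULL)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

# synthetic tiled gene annotation over the SNP span (one gene per 50 kb)
.tiled_genes <- function(snps) {
  out <- NULL
  for (chr in unique(snps$chrom)) {
    pos <- snps$pos[snps$chrom == chr]
    starts <- seq(1, max(pos), by = 5e4)
    out <- rbind(out, data.frame(
      gene_id = sprintf("gene_%s_%04d", chr, seq_along(starts)),
      chrom = chr, start = starts, end = starts + 2e4,
      stringsAsFactors = FALSE))
  }
  out
}

# demo gene sets: disjoint chunks of the background universe
.demo_gene_sets <- function(background, n_sets = 10, seed = 1) {
  set.seed(seed)
  g <- sample(background)
  chunks <- split(g, cut(seq_along(g), n_sets, labels = FALSE))
  names(chunks) <- sprintf("set%02d", seq_along(chunks))
  lapply(chunks, as.character)
}

# SNP ids within flank_bp of any anchor SNP (same chromosome)
.flank_snps <- function(snps, anchors, flank_bp) {
  hit <- rep(FALSE, nrow(snps))
  for (chr in unique(anchors$chrom)) {
    a <- anchors$pos[anchors$chrom == chr]
    rows <- which(snps$chrom == chr)
    for (p in a)
      hit[rows[abs(snps$pos[rows] - p) <= flank_bp]] <- TRUE
  }
  snps$id[hit]
}

#' Human-readable summary of a pipeline run
#'
#' Re-reads the tables referenced by a manifest and formats the top
#' outliers per scan, the gene intersection, the enrichment table and
#' the association results, in the layout of a supplementary-table
#' report.  Regenerating the report from the same manifest is
#' idempotent.
#'
#' @param manifest list returned by [run_pipeline()] (or read back from
#'   `manifest.json`).
#' @param top_n rows shown per scan.
#' @return Character vector of report lines.
#' @export
make_report <- function(manifest, top_n = 10) {
  lines <- c("altsel pipeline report",
             sprintf("seed: %s", manifest$seed), "")
  for (scan in c("fst", "lsbl", "ihs", "xpclr")) {
    path <- manifest$outputs[[scan]]
    if (is.null(path) || !file.exists(path)) next
    tab <- read_score_table(path)
    o <- order(-abs(tab$value))
    top <- utils::head(tab[o, ], top_n)
    lines <- c(lines, sprintf("== top %s ==", toupper(scan)),
               sprintf("%s\t%s\t%s\t%.6g", top$unit_id, top$chrom,
                       top$pos, top$value), "")
  }
  n_out <- sum(lengths(manifest$outlier_ids))
  if (n_out == 0)
    lines <- c(lines, "zero outlier candidates called", "")
  st <- manifest$stages$association
  if (!is.null(st))
    lines <- c(lines,
               sprintf("Kruskal-Wallis H = %.4g, p = %.4g",
                       st$kruskal_H, st$kruskal_p),
               sprintf("pseudo-heritability = %.3f",
                       st$pseudo_heritability))
  lines
}
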