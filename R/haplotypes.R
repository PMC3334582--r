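#' Construct a phased haplotype matrix
#'
#' Substrate for EHH/iHS and core-haplotype analysis: binary alleles per
#' haplotype x SNP, two haplotypes per sample.  Before polarization the
#' 0/1 codes refer to `allele0`/`allele1` base letters; after
#' [polarize()] code 0 is the ancestral and 1 the derived allele.
#'
#' @param alleles integer matrix (haplotypes x SNPs) of 0/1, `NA` allowed
#'   for missing.
#' @param snps data frame with `id`, `chrom`, `pos`, `allele0`,
#'   `allele1`.
#' @param sample_id sample id per haplotype (each appearing twice).
#' @param population population label per haplotype.
#' @param map optional companion `genetic_map`.
#' @param polarized logical; `TRUE` once 0 = ancestral.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, snps, sample_id, population,
                             map = NULL, polarized = FALSE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2 != 0)
    stop("haplotype count must be even (two per sample)")
  if (nrow(alleles) != length(sample_id) ||
      nrow(alleles) != length(population))
    stop("sample_id/population length must equal haplotype count")
  if (ncol(alleles) != nrow(snps))
    stop("allele columns do not match snps")
  bad <- alleles[!is.na(alleles) & !(alleles %in% 0:1)]
  if (length(bad) > 0) stop("haplotype alleles must be 0/1")
  if (is.unsorted(snps$pos)) stop("SNPs must be position-sorted")
  colnames(alleles) <- snps$id
  structure(list(alleles = alleles, snps = snps,
                 sample_id = as.character(sample_id),
                 population = as.character(population),
                 map = map, polarized = polarized),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "SNPs",
      if (isTRUE(x$polarized)) "(polarized)" else "(unpolarized)", "\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$population)),
                    table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a haplotype matrix by SNP index
#' @param hm a `haplotype_matrix`.
#' @param snp_idx integer or logical index over SNPs.
#' @return The subsetted `haplotype_matrix`.
#' @export
hm_subset_snps <- function(hm, snp_idx) {
  haplotype_matrix(hm$alleles[, snp_idx, drop = FALSE],
                   hm$snps[snp_idx, , drop = FALSE],
                   hm$sample_id, hm$population, hm$map, hm$polarized)
}

#' Subset a haplotype matrix to one population's haplotypes
#' @param hm a `haplotype_matrix`.
#' @param population population label.
#' @return The subsetted `haplotype_matrix`.
#' @export
hm_subset_pop <- function(hm, population) {
  rows <- which(hm$population %in% population)
  if (length(rows) == 0) stop("unknown population: ", population)
  haplotype_matrix(hm$alleles[rows, , drop = FALSE], hm$snps,
                   hm$sample_id[rows], hm$population[rows], hm$map,
                   hm$polarized)
}

#' Derived-allele (or allele-1) frequency per SNP in one population
#' @param hm a `haplotype_matrix`.
#' @param population population label, or `NULL` for all haplotypes.
#' @return Numeric vector of frequencies over called haplotypes.
#' @export
hm_freq <- function(hm, population = NULL) {
  rows <- if (is.null(population)) seq_len(nrow(hm$alleles)) else
    which(hm$population == population)
  if (length(rows) == 0) stop("unknown population: ", population)
  colMeans(hm$alleles[rows, , drop = FALSE], na.rm = TRUE)
}

#' Assign ancestral alleles from outgroup species
#'
#' A SNP keeps an unambiguous ancestral call when the covered (non-
#' missing) outgroups all carry the same allele and that allele is one of
#' the two segregating human alleles; the outgroup priority order
#' (first column highest, e.g. chimp > orangutan > macaque) only matters
#' when higher-priority outgroups are missing - any disagreement among
#' covered outgroups discards the SNP.  Columns whose ancestral allele
#' is `allele1` are flipped so 0 = ancestral, 1 = derived.
#'
#' @param hm_raw an unpolarized `haplotype_matrix`.
#' @param outgroup_table data frame from [read_outgroup_table()]:
#'   `snp_id` plus one base-letter column per outgroup, ordered by
#'   priority.
#' @return List with `hm` (polarized, ambiguous SNPs dropped) and
#'   `removed` (character vector of removed SNP ids).
#' @export
polarize <- function(hm_raw, outgroup_table) {
  if (nrow(outgroup_table) == 0) stop("empty outgroup table")
  og <- outgroup_table[match(hm_raw$snps$id, outgroup_table$snp_id), -1,
                       drop = FALSE]
  og <- as.matrix(og)
  m <- nrow(hm_raw$snps)
  ancestral <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    covered <- og[j, !is.na(og[j, ]) & og[j, ] != "."]
    if (length(covered) == 0) next
    u <- unique(covered)
    if (length(u) > 1) next                       # outgroup conflict
    if (!(u %in% c(hm_raw$snps$allele0[j], hm_raw$snps$allele1[j]))) next
    ancestral[j] <- u
  }
  keep <- !is.na(ancestral)
  removed <- hm_raw$snps$id[!keep]
  alleles <- hm_raw$alleles[, keep, drop = FALSE]
  snps <- hm_raw$snps[keep, , drop = FALSE]
  anc <- ancestral[keep]
  flip <- anc == snps$allele1
  if (any(flip)) {
    alleles[, flip] <- 1L - alleles[, flip]
    a0 <- snps$allele0[flip]
    snps$allele0[flip] <- snps$allele1[flip]
    snps$allele1[flip] <- a0
  }
  hm <- haplotype_matrix(alleles, snps, hm_raw$sample_id,
                         hm_raw$population, hm_raw$map, polarized = TRUE)
  list(hm = hm, removed = removed)
}

#' Minor-allele-frequency filter across named populations
#'
#' A SNP is retained only when its minor allele frequency is at least
#' `min_maf` in every listed population; SNPs rarer than the cutoff in
#' either population are removed (strict "less than" removal, so a SNP
#' at exactly the cutoff stays).
#'
#' @param hm a `haplotype_matrix`.
#' @param min_maf MAF cutoff (default 0.05).
#' @param populations population labels the rule applies to (default all
#'   populations present).
#' @return The filtered `haplotype_matrix` with attribute
#'   `snps_removed`.
#' @export
maf_filter <- function(hm, min_maf = 0.05, populations = NULL) {
  if (is.null(populations)) populations <- unique(hm$population)
  unknown <- setdiff(populations, unique(hm$population))
  if (length(unknown) > 0)
    stop("unknown population label: ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, ncol(hm$alleles))
  for (pop in populations) {
    f <- hm_freq(hm, pop)
    maf <- pmin(f, 1 - f)
    keep <- keep & maf >= min_maf
  }
  out <- hm_subset_snps(hm, keep)
  attr(out, "snps_removed") <- hm$snps$id[!keep]
  out
}

#' Collapse haplotypes to a genotype matrix
#'
#' Sums the two haplotypes of each sample into a dosage of the 1-coded
#' (derived, if polarized) allele.
#'
#' @param hm a `haplotype_matrix`.
#' @return A `genotype_matrix`.
#' @export
hm_to_genotype_matrix <- function(hm) {
  n_hap <- nrow(hm$alleles)
  ids <- hm$sample_id[seq(1, n_hap, by = 2)]
  pops <- hm$population[seq(1, n_hap, by = 2)]
  dos <- hm$alleles[seq(1, n_hap, by = 2), , drop = FALSE] +
    hm$alleles[seq(2, n_hap, by = 2), , drop = FALSE]
  snps <- data.frame(id = hm$snps$id, chrom = hm$snps$chrom,
                     pos = hm$snps$pos, ref = hm$snps$allele0,
                     alt = hm$snps$allele1, stringsAsFactors = FALSE)
  genotype_matrix(dos, snps,
                  data.frame(id = ids, population = pops,
                             stringsAsFactors = FALSE))
}
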