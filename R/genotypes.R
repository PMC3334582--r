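#' Construct a genotype matrix
#'
#' The universal substrate of the pipeline: a samples x SNPs matrix of
#' diploid allele dosages (0, 1, 2 copies of the counted allele, `NA` for
#' missing) together with per-SNP and per-sample metadata.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; values
#'   must be 0, 1, 2 or `NA`.
#' @param snps data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`.  Rows must match the columns of `dosage` and SNPs must
#'   be sorted by (chrom, pos).
#' @param samples data frame with columns `id`, `population`, and optionally
#'   `sex`, `age`, `altitude`.  Rows must match the rows of `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("sex", "age", "altitude")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA
  }
  gm <- structure(list(dosage = dosage, snps = snps, samples = samples),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  rownames(gm$dosage) <- samples$id
  colnames(gm$dosage) <- snps$id
  gm
}

validate_genotype_matrix <- function(gm) {
  d <- gm$dosage
  if (nrow(d) != nrow(gm$samples))
    stop("dosage rows (", nrow(d), ") do not match samples (",
         nrow(gm$samples), ")")
  if (ncol(d) != nrow(gm$snps))
    stop("dosage columns (", ncol(d), ") do not match snps (",
         nrow(gm$snps), ")")
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad) > 0)
    stop("dosage values must be 0, 1, 2 or NA; found ", bad[1])
  if (anyDuplicated(gm$samples$id))
    stop("duplicated sample identifiers")
  if (anyDuplicated(gm$snps$id))
    stop("duplicated SNP identifiers")
  if (any(gm$snps$pos < 1))
    stop("SNP positions must be 1-based (>= 1)")
  ord <- order(gm$snps$chrom, gm$snps$pos)
  if (!identical(ord, seq_len(nrow(gm$snps))))
    stop("SNPs must be sorted by (chrom, pos)")
  same <- !is.na(gm$snps$ref) & gm$snps$ref == gm$snps$alt
  if (any(same))
    stop("ref and alt allele identical for SNP ", gm$snps$id[which(same)[1]])
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$samples$population)),
                    table(x$samples$population)), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample ids or logical/integer index over samples.
#' @param snps SNP ids or logical/integer index over SNPs.
#' @return The subsetted `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, snps = NULL) {
  si <- seq_len(nrow(gm$samples))
  vi <- seq_len(nrow(gm$snps))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples$id) else
      si[samples]
    if (anyNA(si)) stop("unknown sample id")
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, gm$snps$id) else vi[snps]
    if (anyNA(vi)) stop("unknown SNP id")
  }
  genotype_matrix(gm$dosage[si, vi, drop = FALSE],
                  gm$snps[vi, , drop = FALSE],
                  gm$samples[si, , drop = FALSE])
}

#' Counted-allele frequency in one population
#'
#' Frequency of the counted allele at a SNP among the called genotypes of
#' one population (or the whole cohort).
#'
#' @param gm a `genotype_matrix`.
#' @param population population label, or `NULL` for all samples.
#' @param snp SNP id or column index.
#' @return List with `freq` and `n_called_alleles`.
#' @export
allele_freq <- function(gm, population = NULL, snp) {
  j <- if (is.character(snp)) match(snp, gm$snps$id) else snp
  if (is.na(j)) stop("unknown SNP: ", snp)
  rows <- if (is.null(population)) seq_len(nrow(gm$dosage)) else
    which(gm$samples$population == population)
  d <- gm$dosage[rows, j]
  n <- sum(!is.na(d))
  if (n == 0) stop("zero called genotypes at SNP ", gm$snps$id[j])
  list(freq = sum(d, na.rm = TRUE) / (2 * n), n_called_alleles = 2L * n)
}

#' Per-SNP allele frequencies for a set of samples
#'
#' Vectorized companion to [allele_freq()]: counted-allele frequency at
#' every SNP over the given rows.  SNPs with no called genotype get `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @param rows integer or logical index of samples (default all).
#' @return Numeric vector of frequencies, one per SNP.
#' @export
allele_freqs <- function(gm, rows = NULL) {
  d <- if (is.null(rows)) gm$dosage else gm$dosage[rows, , drop = FALSE]
  n <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n)
  f[n == 0] <- NA_real_
  f
}

#' Genotype quality-control filter
#'
#' Removes SNPs with completeness below `snp_call_min` (kept when
#' completeness is at least the threshold), then samples whose call rate
#' over the surviving SNPs is not strictly above `sample_call_min`.  The
#' SNP rule is inclusive and the sample rule strict, reflecting the usual
#' array-QC phrasing ("at least 95%" vs "> 95%").
#'
#' @param gm a `genotype_matrix`.
#' @param snp_call_min minimum SNP completeness fraction (default 0.95).
#' @param sample_call_min sample call-rate threshold, strict (default 0.95).
#' @param verbose log removal counts with `message()`.
#' @return The filtered `genotype_matrix`, with attributes
#'   `snps_removed` and `samples_removed` holding removed ids.
#' @export
qc_filter <- function(gm, snp_call_min = 0.95, sample_call_min = 0.95,
                      verbose = FALSE) {
  called <- !is.na(gm$dosage)
  snp_rate <- colMeans(called)
  keep_snp <- snp_rate >= snp_call_min
  if (!any(keep_snp)) stop("qc_filter removed every SNP")
  snps_removed <- gm$snps$id[!keep_snp]
  called <- called[, keep_snp, drop = FALSE]
  sample_rate <- rowMeans(called)
  keep_sample <- sample_rate > sample_call_min
  if (!any(keep_sample)) stop("qc_filter removed every sample")
  samples_removed <- gm$samples$id[!keep_sample]
  if (verbose)
    message("qc_filter: removed ", length(snps_removed), " SNPs and ",
            length(samples_removed), " samples")
  out <- gm_subset(gm, samples = keep_sample, snps = keep_snp)
  attr(out, "snps_removed") <- snps_removed
  attr(out, "samples_removed") <- samples_removed
  out
}
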