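#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) keeping biallelic SNP records
#' only; multi-allelic or indel records are skipped and counted.  Dosage
#' counts the ALT allele.  When `phased_required` is `TRUE` every called
#' genotype must use the phased separator `|`, and the phased haplotypes
#' are returned alongside the dosages.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param phased_required require phased genotypes and return haplotypes.
#' @param verbose log the skipped-record count.
#' @return A `genotype_matrix`.  Attribute `n_skipped` carries the number
#'   of non-biallelic-SNP records dropped; when `phased_required`,
#'   attribute `haplotypes` holds a 2n x m 0/1 matrix (rows
#'   `<sample>_1`, `<sample>_2`).
#' @export
read_vcf <- function(path, phased_required = FALSE, verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (verbose && n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP records")
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  sample_ids <- colnames(gt)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids in ", path)

  called <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  if (phased_required && any(grepl("/", gt[called], fixed = TRUE)))
    stop("phased genotypes required but unphased separator '/' found")

  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  if (any(!is.na(dos) & dos > 2)) stop("GT allele index > 1 in biallelic record")

  snps <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  noid <- is.na(snps$id) | snps$id == "."
  snps$id[noid] <- paste0(snps$chrom[noid], ":", snps$pos[noid])
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  dos <- dos[ord, , drop = FALSE]

  samples <- data.frame(id = sample_ids, population = "unknown",
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(dos), snps, samples)
  attr(gm, "n_skipped") <- n_skipped
  if (phased_required) {
    h1 <- suppressWarnings(matrix(as.integer(a1), nrow(gt), ncol(gt)))[ord, ,
                                                                       drop = FALSE]
    h2 <- suppressWarnings(matrix(as.integer(a2), nrow(gt), ncol(gt)))[ord, ,
                                                                       drop = FALSE]
    hap <- matrix(NA_integer_, 2 * length(sample_ids), nrow(snps))
    hap[seq(1, 2 * length(sample_ids), by = 2), ] <- t(h1)
    hap[seq(2, 2 * length(sample_ids), by = 2), ] <- t(h2)
    rownames(hap) <- paste0(rep(sample_ids, each = 2), "_", 1:2)
    colnames(hap) <- snps$id
    attr(gm, "haplotypes") <- hap
  }
  gm
}

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only genotypes.  If `haplotypes`
#' is supplied (2n x m, 0/1) phased genotypes are written, otherwise
#' unphased genotypes consistent with the dosages.
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @param haplotypes optional phased 0/1 haplotype matrix, two rows per
#'   sample in sample order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, haplotypes = NULL) {
  n <- nrow(gm$samples)
  m <- nrow(gm$snps)
  sep <- if (is.null(haplotypes)) "/" else "|"
  if (is.null(haplotypes)) {
    d <- t(gm$dosage)                      # snps x samples
    gt <- matrix("./.", m, n)
    gt[!is.na(d) & d == 0] <- "0/0"
    gt[!is.na(d) & d == 1] <- "0/1"
    gt[!is.na(d) & d == 2] <- "1/1"
  } else {
    if (nrow(haplotypes) != 2 * n || ncol(haplotypes) != m)
      stop("haplotypes must be 2*n_samples x n_snps")
    h1 <- t(haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE])
    h2 <- t(haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE])
    gt <- matrix(paste0(h1, "|", h2), m, n)
    gt[is.na(h1) | is.na(h2)] <- ".|."
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=altsel",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples$id), collapse = "\t"))
  body <- cbind(gm$snps$chrom, gm$snps$pos, gm$snps$id, gm$snps$ref,
                gm$snps$alt, ".", "PASS", ".", "GT", gt)
  lines <- c(header, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
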