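#' Read a PLINK 1.x binary fileset
#'
#' Decodes `prefix.bed`/`.bim`/`.fam` (SNP-major mode only).  The 2-bit
#' codes are mapped per the PLINK v1 format: `00` = homozygous A1,
#' `01` = missing, `10` = heterozygous, `11` = homozygous A2.  By default
#' the dosage counts the A1 allele (PLINK's minor-allele convention);
#' `count_allele = "A2"` flips to A2-counting, which matches VCF
#' ALT-counting when A2 is the REF... conversely use it for parity tests.
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triple.
#' @param count_allele which allele the dosage counts, `"A1"` (default)
#'   or `"A2"`.
#' @return A `genotype_matrix` (ref = the non-counted allele, alt = the
#'   counted allele).
#' @export
read_plink_bed <- function(prefix, count_allele = c("A1", "A2")) {
  count_allele <- match.arg(count_allele)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss) > 0) stop("missing file(s): ", paste(miss, collapse = ", "))

  bim <- utils::read.table(paths[2], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  fam <- utils::read.table(paths[3], header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  m <- nrow(bim)
  n <- nrow(fam)

  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad .bed magic bytes in ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3 != bytes_per_snp * m)
    stop(".bed payload size does not match .bim/.fam dimensions")

  payload <- raw[-(1:3)]
  bits <- matrix(as.integer(rawToBits(payload)), nrow = 8)
  # two-bit codes, sample-fastest within each SNP's byte block
  code <- bits[seq(1, 8, by = 2), ] + 2L * bits[seq(2, 8, by = 2), ]
  code <- matrix(as.vector(code), nrow = 4 * bytes_per_snp)[1:n, ,
                                                            drop = FALSE]
  # code: 0 = hom A1, 1 = missing, 2 = het, 3 = hom A2
  dos_a1 <- c(2L, NA_integer_, 1L, 0L)[code + 1L]
  dos <- matrix(dos_a1, nrow = n, ncol = m)
  if (count_allele == "A2") dos <- 2L - dos

  counted <- if (count_allele == "A1") bim$a1 else bim$a2
  other <- if (count_allele == "A1") bim$a2 else bim$a1
  snps <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                     ref = other, alt = counted, stringsAsFactors = FALSE)
  ord <- order(snps$chrom, snps$pos)
  samples <- data.frame(id = fam$iid, population = fam$fid,
                        sex = c("male", "female")[match(fam$sex, 1:2)],
                        stringsAsFactors = FALSE)
  genotype_matrix(dos[, ord, drop = FALSE], snps[ord, , drop = FALSE],
                  samples)
}

#' Write a genotype matrix as a PLINK 1.x binary fileset
#'
#' Emits SNP-major `.bed` plus `.bim`/`.fam`.  The counted (alt) allele
#' is written as A1 so that a round trip through [read_plink_bed()] with
#' the default `count_allele = "A1"` reproduces the dosages.
#'
#' @param gm a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_bed <- function(gm, prefix) {
  n <- nrow(gm$samples)
  m <- nrow(gm$snps)
  d <- gm$dosage
  # dosage of A1: 2 -> code 0, 1 -> code 2, 0 -> code 3, NA -> code 1
  code <- matrix(1L, n, m)
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  # interleave low/high bit per sample: byte = s1lo s1hi s2lo s2hi ...
  bits <- matrix(0L, 2 * nrow(code), ncol(code))
  bits[seq(1, nrow(bits), by = 2), ] <- code %% 2L
  bits[seq(2, nrow(bits), by = 2), ] <- code %/% 2L
  payload <- packBits(as.vector(bits) > 0, type = "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(payload, con)

  bim <- data.frame(gm$snps$chrom, gm$snps$id, 0, gm$snps$pos,
                    gm$snps$alt, gm$snps$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  sex <- match(gm$samples$sex, c("male", "female"))
  sex[is.na(sex)] <- 0
  fam <- data.frame(gm$samples$population, gm$samples$id, 0, 0, sex, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
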