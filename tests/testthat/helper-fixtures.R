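# shared fixture builders (all data generated in code)

# genotype matrix from a samples x SNPs dosage matrix
toy_gm <- function(dosage, populations = NULL, chrom = "1",
                   pos = NULL, ref = "A", alt = "G") {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(populations)) populations <- rep("A", n)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(dosage,
                  snps = data.frame(id = sprintf("s%03d", seq_len(m)),
                                    chrom = chrom, pos = pos,
                                    ref = ref, alt = alt,
                                    stringsAsFactors = FALSE),
                  samples = data.frame(id = sprintf("i%03d", seq_len(n)),
                                       population = populations,
                                       stringsAsFactors = FALSE))
}

# haplotype matrix from a haplotypes x SNPs 0/1 matrix
toy_hm <- function(alleles, populations = NULL, pos = NULL,
                   map = NULL, polarized = TRUE, chrom = "1") {
  alleles <- as.matrix(alleles)
  nh <- nrow(alleles); m <- ncol(alleles)
  if (is.null(populations)) populations <- rep("A", nh)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  haplotype_matrix(alleles,
                   snps = data.frame(id = sprintf("s%03d", seq_len(m)),
                                     chrom = chrom, pos = pos,
                                     allele0 = "A", allele1 = "G",
                                     stringsAsFactors = FALSE),
                   sample_id = rep(sprintf("i%03d", seq_len(nh / 2)),
                                   each = 2),
                   population = populations, map = map,
                   polarized = polarized)
}

# independent Weir-Cockerham (1984) two-population oracle, written
# directly from the variance-component definitions on genotype vectors
wc84_oracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB); r <- 2
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# brute-force EHH oracle: probability two random carriers are identical
# over every SNP between the core and the offset SNP (inclusive)
ehh_oracle <- function(alleles, carriers, core, to) {
  rng <- if (to >= core) core:to else to:core
  strings <- apply(alleles[carriers, rng, drop = FALSE], 1, paste,
                   collapse = "")
  cnt <- table(strings)
  n <- length(carriers)
  sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
}

# write a small VCF text fixture; gts is a SNPs x samples matrix of GT
# strings
write_vcf_fixture <- function(path, gts, chrom = "1",
                              pos = NULL, ref = "A", alt = "G",
                              ids = NULL) {
  m <- nrow(gts); n <- ncol(gts)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ids)) ids <- sprintf("rs%d", seq_len(m))
  ref <- rep_len(ref, m); alt <- rep_len(alt, m)
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT",
                     sprintf("smp%02d", seq_len(n))), collapse = "\t"))
  for (i in seq_len(m))
    lines <- c(lines, paste(c(chrom, pos[i], ids[i], ref[i], alt[i],
                              ".", "PASS", ".", "GT", gts[i, ]),
                            collapse = "\t"))
  writeLines(lines, path)
  path
}
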