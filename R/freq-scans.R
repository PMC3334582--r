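#' Weir-Cockerham F_ST scan over all SNPs
#'
#' Two-population Weir-Cockerham (1984) theta-hat per SNP, computed from
#' the called sample sizes, allele frequencies and observed
#' heterozygosities via the a/b/c variance components.  The raw value is
#' returned and may be negative; SNPs monomorphic in both populations
#' (a + b + c = 0) or with fewer than 2 called genotypes in either
#' population are unestimable and get `NA`.
#'
#' @param gm a `genotype_matrix`.
#' @param popA,popB population labels.
#' @return Numeric vector of theta-hat per SNP (`NA` = unestimable).
#' @export
wc_fst_scan <- function(gm, popA, popB) {
  dA <- gm$dosage[gm$samples$population == popA, , drop = FALSE]
  dB <- gm$dosage[gm$samples$population == popB, , drop = FALSE]
  if (nrow(dA) == 0 || nrow(dB) == 0) stop("unknown population label")
  nA <- colSums(!is.na(dA))
  nB <- colSums(!is.na(dB))
  pA <- colSums(dA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(dA == 1, na.rm = TRUE) / nA
  hB <- colSums(dB == 1, na.rm = TRUE) / nB

  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  theta <- a / (a + b + cc)
  theta[!is.finite(theta)] <- NA_real_
  theta[nA < 2 | nB < 2] <- NA_real_
  theta[a + b + cc == 0] <- NA_real_
  unname(theta)
}

#' Weir-Cockerham F_ST at one SNP
#'
#' @param gm a `genotype_matrix`.
#' @param popA,popB population labels.
#' @param snp SNP id or column index.
#' @return theta-hat (may be negative), or `NA` when unestimable.
#' @export
wc_fst <- function(gm, popA, popB, snp) {
  j <- if (is.character(snp)) match(snp, gm$snps$id) else snp
  if (is.na(j)) stop("unknown SNP: ", snp)
  wc_fst_scan(gm_subset(gm, snps = j), popA, popB)
}

#' Pairwise F_ST branch distances for three populations
#'
#' Per-SNP pairwise Weir-Cockerham F_ST between the focal population A
#' and references B and C, the substrate of the locus-specific branch
#' length.
#'
#' @param gm a `genotype_matrix` containing the three populations.
#' @param pops character vector of the three population labels, in
#'   (A, B, C) order.
#' @return Data frame with columns `snp_id`, `chrom`, `pos`, `d_AB`,
#'   `d_AC`, `d_BC` (`NA` = unestimable).
#' @export
pairwise_distances <- function(gm, pops = c("A", "B", "C")) {
  if (length(pops) != 3) stop("exactly three populations required")
  data.frame(snp_id = gm$snps$id, chrom = gm$snps$chrom,
             pos = gm$snps$pos,
             d_AB = wc_fst_scan(gm, pops[1], pops[2]),
             d_AC = wc_fst_scan(gm, pops[1], pops[3]),
             d_BC = wc_fst_scan(gm, pops[2], pops[3]),
             stringsAsFactors = FALSE)
}

#' Locus-specific branch length
#'
#' LSBL of the focal population on the three-population star tree:
#' (d_AB + d_AC - d_BC) / 2 with pairwise F_ST as branch distances.
#' Negative input distances are clamped to 0 before combination
#' (distances on a tree cannot be negative); SNPs with any unestimable
#' distance are skipped (`NA`).
#'
#' @param d data frame from [pairwise_distances()].
#' @param focal which population is focal: `"A"` (default), `"B"` or
#'   `"C"`.
#' @return Numeric LSBL per SNP.
#' @export
lsbl <- function(d, focal = "A") {
  ab <- pmax(d$d_AB, 0)
  ac <- pmax(d$d_AC, 0)
  bc <- pmax(d$d_BC, 0)
  out <- switch(focal,
                A = (ab + ac - bc) / 2,
                B = (ab + bc - ac) / 2,
                C = (ac + bc - ab) / 2,
                stop("focal must be A, B or C"))
  out[is.na(d$d_AB) | is.na(d$d_AC) | is.na(d$d_BC)] <- NA_real_
  out
}

#' Empirical top-fraction outlier calling
#'
#' Threshold = the value at rank ceiling((1 - fraction) * N) of the
#' sorted finite values (nearest-rank quantile); outliers are the
#' entries STRICTLY greater than the threshold, matching the
#' "statistic > threshold" convention of empirical scans.  With
#' `use_absolute` the absolute value is ranked (as for iHS).
#'
#' @param table a `score_table`.
#' @param fraction top fraction (default 0.001).
#' @param use_absolute rank `|value|` instead of `value`.
#' @return List with `threshold` and `outliers` (unit ids).
#' @export
empirical_top <- function(table, fraction = 0.001, use_absolute = FALSE) {
  if (nrow(table) == 0) stop("empty score table")
  v <- table$value
  if (use_absolute) v <- abs(v)
  fin <- is.finite(v)
  N <- sum(fin)
  if (N < 1 / fraction)
    warning("only ", N, " finite values for top fraction ", fraction)
  sv <- sort(v[fin])
  thr <- sv[ceiling((1 - fraction) * N)]
  list(threshold = thr,
       outliers = table$unit_id[fin & v > thr])
}
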