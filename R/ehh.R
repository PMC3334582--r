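# internal: one-sided EHH walk from a core SNP.
# Returns offsets (cM, >= 0), EHH values (starting at the core, EHH = 1),
# and whether the walk was truncated by the chromosome edge or a large
# physical gap before decaying below ehh_min.
.ehh_side <- function(alleles, carriers, core_idx, side, cm, pos,
                      ehh_min = 0.05, max_gap_bp = 2e5) {
  n_c <- length(carriers)
  denom <- n_c * (n_c - 1) / 2
  step <- if (side == "left") -1L else 1L
  g <- rep(1L, n_c)
  offs <- 0
  vals <- 1
  j <- core_idx
  truncated <- FALSE
  repeat {
    nxt <- j + step
    if (nxt < 1 || nxt > ncol(alleles)) {            # chromosome end
      truncated <- TRUE
      break
    }
    if (abs(pos[nxt] - pos[j]) > max_gap_bp) {       # large gap
      truncated <- TRUE
      break
    }
    a <- alleles[carriers, nxt]
    a[is.na(a)] <- 2L                                # missing = own class
    g <- g * 3L + a
    g <- match(g, unique(g))                         # keep ids small
    cnt <- tabulate(g)
    ehh_val <- sum(cnt * (cnt - 1) / 2) / denom
    offs <- c(offs, abs(cm[nxt] - cm[core_idx]))
    vals <- c(vals, ehh_val)
    j <- nxt
    if (ehh_val < ehh_min) break
  }
  list(offset_cM = offs, ehh = vals, truncated = truncated)
}

#' Extended haplotype homozygosity curve from a core SNP
#'
#' EHH at map offset x is the probability that two random haplotypes
#' carrying the core allele are identical at every SNP between the core
#' and x: sum over identity classes h of C(n_h, 2) / C(n_c, 2).  The
#' walk proceeds SNP by SNP away from the core until EHH drops below
#' `ehh_min` (default 0.05), the chromosome ends, or a physical gap
#' larger than `max_gap_bp` (default 200 kb) is met; in the latter two
#' cases the side is flagged truncated.
#'
#' @param hm a polarized `haplotype_matrix` with a companion map (bp
#'   positions are converted at a constant rate of 1 cM/Mb when no map
#'   is attached).
#' @param core_snp SNP id or index.
#' @param core_allele `"derived"` (1) or `"ancestral"` (0).
#' @param direction `"both"` (default), `"left"` or `"right"`.
#' @param ehh_min decay cutoff.
#' @param max_gap_bp gap rule.
#' @param population restrict to one population's haplotypes.
#' @return List of class `ehh_curve`: `left`/`right` data frames
#'   (`offset_cM`, `ehh`), `truncated_left`, `truncated_right`,
#'   `n_carriers`.
#' @export
ehh <- function(hm, core_snp, core_allele = c("derived", "ancestral"),
                direction = c("both", "left", "right"),
                ehh_min = 0.05, max_gap_bp = 2e5, population = NULL) {
  core_allele <- match.arg(core_allele)
  direction <- match.arg(direction)
  j <- if (is.character(core_snp)) match(core_snp, hm$snps$id) else core_snp
  if (is.na(j)) stop("unknown core SNP")
  rows <- if (is.null(population)) seq_len(nrow(hm$alleles)) else
    which(hm$population == population)
  want <- if (core_allele == "derived") 1L else 0L
  carriers <- rows[!is.na(hm$alleles[rows, j]) & hm$alleles[rows, j] == want]
  if (length(carriers) < 2)
    stop("fewer than 2 carriers of the ", core_allele, " core allele")
  cm <- if (!is.null(hm$map)) interpolate_cm(hm$map, hm$snps$pos) else
    hm$snps$pos / 1e6                                # 1 cM/Mb fallback
  out <- list(left = NULL, right = NULL,
              truncated_left = FALSE, truncated_right = FALSE,
              n_carriers = length(carriers))
  if (direction %in% c("both", "left")) {
    s <- .ehh_side(hm$alleles, carriers, j, "left", cm, hm$snps$pos,
                   ehh_min, max_gap_bp)
    out$left <- data.frame(offset_cM = s$offset_cM, ehh = s$ehh)
    out$truncated_left <- s$truncated
  }
  if (direction %in% c("both", "right")) {
    s <- .ehh_side(hm$alleles, carriers, j, "right", cm, hm$snps$pos,
                   ehh_min, max_gap_bp)
    out$right <- data.frame(offset_cM = s$offset_cM, ehh = s$ehh)
    out$truncated_right <- s$truncated
  }
  class(out) <- "ehh_curve"
  out
}

# trapezoid integral of an EHH side against cM offset
.ihh_side <- function(side_df) {
  x <- side_df$offset_cM
  y <- side_df$ehh
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Unstandardized iHS at one SNP
#'
#' ln(iHH_A / iHH_D) where iHH is the trapezoid integral of the
#' two-sided EHH curve against genetic distance (left + right side,
#' the core contributing the common origin).  Undefined (`NA`) when a
#' side of either allele class was truncated by an edge or gap before
#' decaying, when an allele class has < 2 carriers, or when an integral
#' is zero.
#'
#' @param hm a polarized `haplotype_matrix`.
#' @param snp SNP id or index.
#' @param population restrict to one population's haplotypes.
#' @inheritParams ehh
#' @return ln(iHH_A / iHH_D), or `NA` with attribute `reason`.
#' @export
ihs_unstandardized <- function(hm, snp, population = NULL,
                               ehh_min = 0.05, max_gap_bp = 2e5) {
  res <- tryCatch({
    eA <- ehh(hm, snp, "ancestral", "both", ehh_min, max_gap_bp,
              population)
    eD <- ehh(hm, snp, "derived", "both", ehh_min, max_gap_bp,
              population)
    if (eA$truncated_left || eA$truncated_right ||
        eD$truncated_left || eD$truncated_right)
      return(structure(NA_real_, reason = "truncated"))
    ihh_a <- .ihh_side(eA$left) + .ihh_side(eA$right)
    ihh_d <- .ihh_side(eD$left) + .ihh_side(eD$right)
    if (ihh_a <= 0 || ihh_d <= 0)
      return(structure(NA_real_, reason = "zero_ihh"))
    structure(log(ihh_a / ihh_d), ihh_a = ihh_a, ihh_d = ihh_d)
  }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
  res
}

#' Genome-wide unstandardized iHS scan
#'
#' Runs [ihs_unstandardized()] at every SNP (optionally within one
#' population) and collects derived frequencies and iHH integrals.
#'
#' @param hm a polarized, MAF-filtered `haplotype_matrix`.
#' @param population population label, or `NULL` for all haplotypes.
#' @inheritParams ehh
#' @return Data frame: `snp_id`, `chrom`, `pos`, `derived_freq`,
#'   `ihh_a`, `ihh_d`, `raw` (unstandardized score; `NA` = undefined).
#' @export
ihs_scan <- function(hm, population = NULL, ehh_min = 0.05,
                     max_gap_bp = 2e5) {
  m <- ncol(hm$alleles)
  freq <- hm_freq(hm, population)
  raw <- ihh_a <- ihh_d <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    v <- ihs_unstandardized(hm, j, population, ehh_min, max_gap_bp)
    raw[j] <- as.numeric(v)
    if (!is.na(raw[j])) {
      ihh_a[j] <- attr(v, "ihh_a")
      ihh_d[j] <- attr(v, "ihh_d")
    }
  }
  data.frame(snp_id = hm$snps$id, chrom = hm$snps$chrom,
             pos = hm$snps$pos, derived_freq = freq,
             ihh_a = ihh_a, ihh_d = ihh_d, raw = raw,
             stringsAsFactors = FALSE)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Scores are standardized to zero mean and unit (population) variance
#' within equal-width derived-frequency bins on \[0.05, 0.95\] so that
#' the score is comparable across frequencies.  Bins holding fewer than
#' `min_per_bin` defined scores are merged with their smaller neighbour
#' until every occupied bin is large enough.
#'
#' @param scores unstandardized scores (`NA` allowed; excluded and
#'   returned as `NA`).
#' @param derived_freqs derived allele frequencies, same length.
#' @param n_bins number of equal-width bins (default 20).
#' @param min_per_bin minimum defined scores per bin (default 20).
#' @return Data frame: `raw`, `derived_freq`, `bin` (merged bin id),
#'   `ihs` (standardized score).
#' @export
ihs_standardize <- function(scores, derived_freqs, n_bins = 20,
                            min_per_bin = 20) {
  stopifnot(length(scores) == length(derived_freqs))
  edges <- seq(0.05, 0.95, length.out = n_bins + 1)
  bin <- findInterval(derived_freqs, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin > n_bins] <- n_bins
  ok <- !is.na(scores) & !is.na(derived_freqs)

  # merge sparse occupied bins into their smaller neighbour
  merge_map <- seq_len(n_bins)
  repeat {
    eff <- merge_map[bin[ok]]
    cnt <- table(factor(eff, levels = unique(merge_map)))
    small <- names(cnt)[cnt < min_per_bin & cnt > 0]
    if (length(small) == 0 || length(unique(merge_map)) == 1) break
    b <- as.integer(small[1])
    groups <- sort(unique(merge_map))
    gi <- match(b, groups)
    neigh <- c(if (gi > 1) groups[gi - 1],
               if (gi < length(groups)) groups[gi + 1])
    ncnt <- vapply(neigh, function(g) sum(eff == g), numeric(1))
    tgt <- neigh[which.min(ncnt)]
    merge_map[merge_map == b] <- tgt
  }
  eff_bin <- merge_map[bin]

  ihs <- rep(NA_real_, length(scores))
  for (g in unique(eff_bin[ok])) {
    sel <- ok & eff_bin == g
    x <- scores[sel]
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))                   # population SD
    if (sdev == 0) stop("zero-variance frequency bin ", g)
    ihs[sel] <- (x - mu) / sdev
  }
  data.frame(raw = scores, derived_freq = derived_freqs,
             bin = eff_bin, ihs = ihs)
}

#' Core-haplotype frequencies per population
#'
#' Counts the distinct allele strings over a small set of core SNPs
#' (typically 3) in each population; haplotypes missing any core allele
#' are excluded from the denominator, so frequencies sum to 1 per
#' population.
#'
#' @param hm a phased `haplotype_matrix`.
#' @param core_snp_ids SNP ids (or indices) of the core, on one
#'   chromosome.
#' @param populations populations to tabulate (default all present).
#' @return Data frame: `haplotype` (allele string), `population`,
#'   `count`, `freq`.
#' @export
core_haplotype_freq <- function(hm, core_snp_ids, populations = NULL) {
  idx <- if (is.character(core_snp_ids))
    match(core_snp_ids, hm$snps$id) else core_snp_ids
  if (anyNA(idx)) stop("core SNPs not covered by the haplotype matrix")
  if (length(unique(hm$snps$chrom[idx])) != 1)
    stop("core SNPs must be on one chromosome")
  if (is.null(populations)) populations <- unique(hm$population)
  core <- hm$alleles[, idx, drop = FALSE]
  strings <- apply(core, 1, paste, collapse = "")
  strings[rowSums(is.na(core)) > 0] <- NA
  out <- NULL
  for (pop in populations) {
    s <- strings[hm$population == pop]
    s <- s[!is.na(s)]
    if (length(s) == 0) next
    tab <- table(s)
    out <- rbind(out, data.frame(haplotype = names(tab),
                                 population = pop,
                                 count = as.integer(tab),
                                 freq = as.numeric(tab) / length(s),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
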