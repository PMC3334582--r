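#' Genes within a flanking distance of outlier SNPs
#'
#' A gene is included when the minimum distance from any listed SNP to
#' the gene's \[start, end\] interval is at most `flank_bp` (inclusive
#' at exactly the flank; distance 0 inside the gene).  Chromosome
#' labels must match between SNPs and genes; SNPs on chromosomes absent
#' from the annotation simply match nothing.
#'
#' @param snp_positions data frame with `chrom` and `pos` columns (bp).
#' @param genes gene annotation from [read_bed_genes()] (columns
#'   `gene_id`, `chrom`, `start`, `end`, 1-based inclusive).
#' @param flank_bp flanking distance in bp (default 100000).
#' @return Character vector of gene ids (sorted, unique).
#' @export
genes_near_snps <- function(snp_positions, genes, flank_bp = 100000) {
  hits <- character(0)
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    s <- snp_positions$pos[snp_positions$chrom == chr]
    if (length(s) == 0) next
    for (i in seq_len(nrow(g))) {
      d <- pmax(g$start[i] - s, s - g$end[i], 0)
      if (any(d <= flank_bp)) hits <- c(hits, g$gene_id[i])
    }
  }
  sort(unique(hits))
}

#' Gene-set over-representation by 2x2 chi-square
#'
#' For each set, a plain Pearson chi-square (1 df, no continuity
#' correction) on the 2x2 table of candidate vs non-candidate genes by
#' in-set vs not-in-set, over the background gene universe.  Raw
#' p-values are Bonferroni-corrected by the number of sets tested in
#' the call.  Sets with any expected cell count below 1 are flagged
#' low-confidence but still reported.
#'
#' @param candidates candidate gene ids (must be a subset of
#'   `background`).
#' @param background background gene universe.
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @return Data frame: `set_id`, `n_candidate_in_set`,
#'   `n_candidate_total`, `n_background_in_set`, `n_background_total`,
#'   `chi_square`, `p_raw`, `p_bonferroni`, `low_confidence`.
#' @export
gene_set_chisq <- function(candidates, background, sets) {
  candidates <- unique(candidates)
  background <- unique(background)
  if (length(candidates) == 0) stop("empty candidate list")
  if (length(background) < 2) stop("background must hold >= 2 genes")
  if (!all(candidates %in% background))
    stop("candidates must be a subset of the background")
  n_sets <- length(sets)
  out <- NULL
  for (sid in names(sets)) {
    members <- intersect(sets[[sid]], background)
    a <- sum(candidates %in% members)              # candidate, in set
    b <- length(candidates) - a                    # candidate, not
    c_ <- sum(!(background %in% candidates) & background %in% members)
    d <- length(background) - length(candidates) - c_
    tab <- matrix(c(a, b, c_, d), 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi <- unname(ct$statistic)
      p <- unname(ct$p.value)
      low <- any(ct$expected < 1)
    } else {
      chi <- 0; p <- 1; low <- TRUE
    }
    out <- rbind(out, data.frame(set_id = sid,
                                 n_candidate_in_set = a,
                                 n_candidate_total = length(candidates),
                                 n_background_in_set = a + c_,
                                 n_background_total = length(background),
                                 chi_square = chi, p_raw = p,
                                 p_bonferroni = min(1, p * n_sets),
                                 low_confidence = low,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Genes shared by every scan's candidate list
#'
#' Exact intersection of two or more candidate gene sets, plus a
#' per-gene membership matrix over all scans for reporting.
#'
#' @param gene_sets list of >= 2 character vectors of gene ids.
#' @param labels scan labels (default names of `gene_sets` or
#'   `scan1..k`).
#' @return List with `intersection` (character vector) and `membership`
#'   (logical matrix, genes x scans, covering the union).
#' @export
scan_intersection <- function(gene_sets, labels = NULL) {
  if (length(gene_sets) < 2) stop("need at least two gene sets")
  if (is.null(labels))
    labels <- if (!is.null(names(gene_sets))) names(gene_sets) else
      paste0("scan", seq_along(gene_sets))
  gene_sets <- lapply(gene_sets, unique)
  all_genes <- sort(unique(unlist(gene_sets)))
  membership <- matrix(FALSE, length(all_genes), length(gene_sets),
                       dimnames = list(all_genes, labels))
  for (k in seq_along(gene_sets))
    membership[, k] <- all_genes %in% gene_sets[[k]]
  list(intersection = all_genes[rowSums(membership) == length(gene_sets)],
       membership = membership)
}
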