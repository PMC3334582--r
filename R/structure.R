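#' Squared LD correlation between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over
#' pairwise-complete samples.
#'
#' @param gm a `genotype_matrix`.
#' @param snp_i,snp_j SNP ids or column indices.
#' @return r-squared in \[0, 1\], or `NA` with a warning if either SNP
#'   has zero variance over the shared samples (undefined, distinct
#'   from 0).
#' @export
ld_r2 <- function(gm, snp_i, snp_j) {
  i <- if (is.character(snp_i)) match(snp_i, gm$snps$id) else snp_i
  j <- if (is.character(snp_j)) match(snp_j, gm$snps$id) else snp_j
  x <- gm$dosage[, i]
  y <- gm$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero dosage variance: r2 undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

# r2 matrix over a window of SNP columns, pairwise-complete, NA when
# a variance is zero
.r2_matrix <- function(d) {
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r * r
}

#' Windowed greedy LD pruning
#'
#' PLINK-style pruning: within each sliding window of `window_snps`
#' SNPs, while any pair has r-squared above `r2_max` one member of the
#' worst pair is removed (the one with the lower call rate; ties drop
#' the later position), then the window slides by `step_snps`.
#' Chromosomes are processed independently, so the retained set does
#' not depend on chromosome order.
#'
#' @param gm a `genotype_matrix` (position-sorted, as the class
#'   enforces).
#' @param window_snps window width in SNPs (default 50).
#' @param step_snps slide step in SNPs (default 5).
#' @param r2_max pruning threshold (default 0.5).
#' @return Character vector of retained SNP ids, in genome order.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  keep <- rep(TRUE, nrow(gm$snps))
  call_rate <- colMeans(!is.na(gm$dosage))
  for (chr in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == chr)
    m <- length(idx)
    start <- 1
    repeat {
      end <- min(start + window_snps - 1, m)
      win <- idx[start:end]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- .r2_matrix(gm$dosage[, win, drop = FALSE])
        repeat {
          r2u <- r2
          r2u[lower.tri(r2u, diag = TRUE)] <- NA
          worst <- suppressWarnings(max(r2u, na.rm = TRUE))
          if (!is.finite(worst) || worst <= r2_max) break
          pair <- which(r2u == worst, arr.ind = TRUE)[1, ]
          a <- win[pair[1]]; b <- win[pair[2]]
          drop_local <- if (call_rate[a] < call_rate[b]) pair[1]
          else if (call_rate[b] < call_rate[a]) pair[2]
          else max(pair)                       # tie: later position
          keep[win[drop_local]] <- FALSE
          r2[drop_local, ] <- NA
          r2[, drop_local] <- NA
        }
      }
      if (end >= m) break
      start <- start + step_snps
    }
  }
  gm$snps$id[keep]
}

#' Principal components analysis of genotypes
#'
#' Genotype PCA in the McVean tradition: SNP columns are mean-imputed
#' (per SNP) and centered but NOT variance-scaled; components come from
#' the eigendecomposition of the sample covariance (via SVD of the
#' centered matrix).  Each component's sign is fixed by making its
#' largest-magnitude sample loading positive.
#'
#' @param gm a `genotype_matrix`, typically LD-pruned.
#' @param n_components number of components to return.
#' @return List of class `pca_result`: `coordinates` (samples x
#'   components), `variance_fraction`, `eigenvalues`.
#' @export
pca <- function(gm, n_components = 10) {
  X <- gm$dosage
  if (nrow(X) < 2) stop("need at least 2 samples")
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu)) stop("SNP with all genotypes missing")
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  lambda <- sv$d^2 / (nrow(X) - 1)
  k <- min(n_components, length(lambda))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (c in seq_len(k)) {
    s <- sign(coords[which.max(abs(coords[, c])), c])
    if (s < 0) coords[, c] <- -coords[, c]
  }
  rownames(coords) <- gm$samples$id
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 variance_fraction = lambda[seq_len(k)] / sum(lambda),
                 eigenvalues = lambda),
            class = "pca_result")
}

#' Pairwise pi-hat relatedness (method-of-moments IBD)
#'
#' PLINK-style moment estimator: per pair, observed IBS0/IBS1/IBS2
#' counts over pairwise-complete SNPs are combined with the expected
#' IBS-state probabilities given allele frequencies to solve for
#' P(IBD=0,1,2); pi-hat = P(IBD=2) + P(IBD=1)/2.  Estimates are clipped
#' to \[0, 1\] after computation.  Pairs with fewer than 50 informative
#' SNPs are flagged in the `low_confidence` attribute.
#'
#' @param gm a `genotype_matrix`.
#' @param freqs optional per-SNP counted-allele frequencies; cohort
#'   frequencies are used when `NULL`.
#' @return Symmetric matrix of class `relatedness_matrix` (diagonal 1)
#'   with attribute `low_confidence` (logical matrix).
#' @export
pihat <- function(gm, freqs = NULL) {
  d <- gm$dosage
  n <- nrow(d)
  if (is.null(freqs)) freqs <- allele_freqs(gm)
  p <- freqs
  q <- 1 - p
  # polymorphic, known-frequency SNPs only (monomorphic are uninformative)
  use <- !is.na(p) & p > 0 & p < 1
  d <- d[, use, drop = FALSE]
  p <- p[use]; q <- q[use]

  # expected IBS-state probabilities given IBD state, per SNP
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- 1 - e0_ibd0 - e1_ibd0
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- 1 - e1_ibd1

  ph <- matrix(0, n, n)
  lowconf <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    di <- d[i, ]
    for (j in (i + 1):n) {
      dj <- d[j, ]
      ok <- !is.na(di) & !is.na(dj)
      m <- sum(ok)
      if (m == 0) stop("sample pair with zero shared called SNPs: ",
                       gm$samples$id[i], " / ", gm$samples$id[j])
      if (m < 50) lowconf[i, j] <- lowconf[j, i] <- TRUE
      diff <- abs(di[ok] - dj[ok])
      N0 <- sum(diff == 2)
      N1 <- sum(diff == 1)
      N2 <- sum(diff == 0)
      S0_0 <- sum(e0_ibd0[ok]); S1_0 <- sum(e1_ibd0[ok])
      S2_0 <- sum(e2_ibd0[ok])
      S1_1 <- sum(e1_ibd1[ok]); S2_1 <- sum(e2_ibd1[ok])
      P0 <- N0 / S0_0
      P1 <- (N1 - P0 * S1_0) / S1_1
      P2 <- (N2 - P0 * S2_0 - P1 * S2_1) / m
      P <- pmax(c(P0, P1, P2), 0)
      if (sum(P) > 0) P <- P / sum(P)
      val <- min(max(P[3] + P[2] / 2, 0), 1)
      ph[i, j] <- ph[j, i] <- val
    }
  }
  diag(ph) <- 1
  rownames(ph) <- colnames(ph) <- gm$samples$id
  structure(ph, low_confidence = lowconf,
            class = c("relatedness_matrix", "matrix", "array"))
}

#' Greedy exclusion of related samples
#'
#' While any pair exceeds the pi-hat threshold, remove the member with
#' the most over-threshold partners (ties: higher mean pi-hat, then
#' input order).
#'
#' @param rel a `relatedness_matrix` from [pihat()].
#' @param threshold pi-hat cutoff, pairs strictly above are related
#'   (default 0.25).
#' @return Character vector of removed sample ids (possibly empty).
#' @export
exclude_related <- function(rel, threshold = 0.25) {
  ph <- unclass(rel)
  diag(ph) <- 0
  active <- rep(TRUE, nrow(ph))
  removed <- character(0)
  repeat {
    over <- ph > threshold & outer(active, active, `&`)
    if (!any(over)) break
    degree <- rowSums(over)
    cand <- which(degree == max(degree))
    if (length(cand) > 1) {
      mp <- rowMeans(ph)[cand]
      cand <- cand[mp == max(mp)]
    }
    pick <- cand[1]                          # remaining tie: input order
    active[pick] <- FALSE
    removed <- c(removed, rownames(ph)[pick])
  }
  removed
}
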