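#' Drift model for the composite-likelihood sweep scan
#'
#' Parameters of the two-population frequency model: a drift variance
#' scale omega linking the reference frequency to the objective
#' population's frequency distribution, the effective population size
#' setting the initial sweep frequency q0 = 1/(2 Ne), and the selection
#' coefficient grid the alternative is maximized over.
#'
#' @param omega drift variance scale (> 0); see [estimate_omega()].
#' @param Ne effective population size (default 15700).
#' @param s_grid selection coefficients searched; default 30 log-spaced
#'   values in \[1e-5, 0.5\] (s = 0, i.e. the null, is always included
#'   implicitly).
#' @param n_quad fixed quadrature points on \[0, 1\] (default 64).
#' @return List of class `xpclr_model`.
#' @export
xpclr_model <- function(omega, Ne = 15700,
                        s_grid = exp(seq(log(1e-5), log(0.5),
                                         length.out = 30)),
                        n_quad = 64) {
  stopifnot(omega > 0, Ne > 0, all(s_grid > 0))
  structure(list(omega = omega, Ne = Ne, q0 = 1 / (2 * Ne),
                 s_grid = sort(s_grid), n_quad = n_quad),
            class = "xpclr_model")
}

#' Method-of-moments drift scale from genome-wide frequencies
#'
#' Matches the across-SNP variance of (pA - pB) to
#' omega * mean(pbar (1 - pbar)), pbar = (pA + pB) / 2, over putatively
#' neutral SNPs.
#'
#' @param freqA,freqB per-SNP allele frequencies in the objective and
#'   reference populations.
#' @return omega (>= 0).
#' @export
estimate_omega <- function(freqA, freqB) {
  ok <- !is.na(freqA) & !is.na(freqB)
  pA <- freqA[ok]; pB <- freqB[ok]
  pbar <- (pA + pB) / 2
  poly <- pbar > 0 & pbar < 1
  if (sum(poly) < 1000)
    warning("omega estimated from only ", sum(poly), " polymorphic SNPs")
  if (!any(poly)) stop("no polymorphic SNPs to estimate omega from")
  mean((pA[poly] - pB[poly])^2) / mean(pbar[poly] * (1 - pbar[poly]))
}

#' LD down-weighting of correlated SNPs
#'
#' SNPs are grouped greedily in position order: a SNP joins the first
#' existing group whose members all have r-squared above `r2_cap` with
#' it (measured in the reference population's haplotypes), else it
#' starts a new group.  Each SNP's weight is 1 / (its group size), so a
#' block of near-duplicate SNPs contributes like a single SNP.
#'
#' @param hap_ref reference-population haplotype 0/1 matrix
#'   (haplotypes x SNPs).
#' @param r2_cap grouping threshold (default 0.95).
#' @return Numeric weights, one per SNP column.
#' @export
ld_weights <- function(hap_ref, r2_cap = 0.95) {
  m <- ncol(hap_ref)
  r2 <- suppressWarnings(stats::cor(hap_ref))^2
  r2[is.na(r2)] <- 0
  group <- integer(m)
  groups <- list()
  for (j in seq_len(m)) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(r2[groups[[gi]], j] > r2_cap)) {
        groups[[gi]] <- c(groups[[gi]], j)
        group[j] <- gi
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- j
      group[j] <- length(groups)
    }
  }
  size <- lengths(groups)
  1 / size[group]
}

# internal: per-SNP marginal log-likelihood pieces shared by all windows.
# Returns quadrature nodes/weights, the truncated-normal drift density
# per SNP (interior weights + boundary masses), binomial likelihoods of
# the observed count at the nodes, and the null log-likelihood.
.xpclr_prepare <- function(kA, nA, pB, model) {
  gq <- pracma::gaussLegendre(model$n_quad, 0, 1)
  x <- gq$x; v <- gq$w
  m <- length(kA)
  # clamp reference frequencies away from 0/1 (degenerate drift density)
  eps <- 0.5 / (2 * model$Ne)
  pB <- pmin(pmax(pB, eps), 1 - eps)
  mu <- pB
  sdv <- sqrt(model$omega * pB * (1 - pB))
  dens <- matrix(0, m, model$n_quad)      # interior mass per node
  m0 <- stats::pnorm(0, mu, sdv)          # boundary point masses
  m1 <- 1 - stats::pnorm(1, mu, sdv)
  for (j in seq_len(m)) {
    w_int <- stats::dnorm(x, mu[j], sdv[j]) * v
    tot <- m0[j] + m1[j] + sum(w_int)
    dens[j, ] <- w_int / tot
    m0[j] <- m0[j] / tot
    m1[j] <- m1[j] / tot
  }
  # binomial likelihood of observed count at each interior node
  lik_nodes <- matrix(0, m, model$n_quad)
  for (j in seq_len(m))
    lik_nodes[j, ] <- stats::dbinom(kA[j], nA, x)
  at0 <- as.numeric(kA == 0)              # Binom(k | n, 0)
  at1 <- as.numeric(kA == nA)             # Binom(k | n, 1)
  L0 <- rowSums(dens * lik_nodes) + m0 * at0 + m1 * at1
  list(x = x, dens = dens, m0 = m0, m1 = m1, at0 = at0, at1 = at1,
       kA = kA, nA = nA, pB = pB, L0 = L0, logL0 = log(L0))
}

# internal: alternative (sweep) log-likelihood of one SNP at escape
# probability c.  A lineage escapes the sweep with probability c and
# keeps its drifted frequency p'; otherwise it is carried by the swept
# background, whose allele is 1 with probability p' and 0 otherwise, so
# the sampling frequency becomes c p' + (1 - c) B.
.xpclr_alt_lik <- function(prep, j, c) {
  if (c >= 1) return(prep$L0[j])
  x <- prep$x
  k <- prep$kA[j]; n <- prep$nA
  lik_hi <- stats::dbinom(k, n, pmin(c * x + (1 - c), 1))
  lik_lo <- stats::dbinom(k, n, pmax(c * x, 0))
  interior <- sum(prep$dens[j, ] * (x * lik_hi + (1 - x) * lik_lo))
  interior + prep$m0[j] * prep$at0[j] + prep$m1[j] * prep$at1[j]
}

#' Composite-likelihood sweep scan over genetic-map windows
#'
#' Slides windows of `window_cm` centimorgans (default 0.005), advanced
#' by `step_bp` base pairs (default 5000), across the region.  For each
#' window the composite log-likelihood of the objective population's
#' allele counts is computed under a drift-only null (truncated-normal
#' frequency distribution around the reference frequency, with boundary
#' point masses) and under a sweep alternative in which a neutral
#' lineage at map distance r Morgans from the window centre escapes the
#' sweep with probability c = 1 - q0^(r/s) and otherwise hitchhikes with
#' the swept background.  The reported score is
#' 2 * (max over the s grid of the alternative log-likelihood minus the
#' null log-likelihood), floored at 0 since s -> 0 recovers the null.
#' SNP contributions are down-weighted by [ld_weights()] groups.
#'
#' @param hm_A objective-population `haplotype_matrix` (polarized), or a
#'   list with elements `kA` (derived counts), `nA`, `pB`, `pos`,
#'   `chrom`.
#' @param hm_B reference-population `haplotype_matrix` (used for
#'   reference frequencies and LD weights); ignored when `hm_A` is a
#'   prepared list.
#' @param map a `genetic_map`.
#' @param model an [xpclr_model()]; when `NULL`, omega is estimated
#'   from the data by [estimate_omega()] and defaults are used.
#' @param window_cm window width in cM.
#' @param step_bp distance between window starts in bp.
#' @param r2_cap LD-grouping threshold.
#' @param min_snps windows with fewer usable SNPs are skipped.
#' @return Data frame: `chrom`, `start_bp`, `end_bp`, `mid_bp`,
#'   `cM_start`, `cM_end`, `n_snps`, `score`, `s_hat`.
#' @export
xpclr_scan <- function(hm_A, hm_B = NULL, map, model = NULL,
                       window_cm = 0.005, step_bp = 5000,
                       r2_cap = 0.95, min_snps = 2) {
  if (inherits(hm_A, "haplotype_matrix")) {
    rows_A <- seq_len(nrow(hm_A$alleles))
    kA <- colSums(hm_A$alleles[rows_A, , drop = FALSE], na.rm = TRUE)
    nA <- nrow(hm_A$alleles)
    pB <- hm_freq(hm_B)
    pos <- hm_A$snps$pos
    chrom <- hm_A$snps$chrom[1]
    wts <- ld_weights(hm_B$alleles, r2_cap)
  } else {
    kA <- hm_A$kA; nA <- hm_A$nA; pB <- hm_A$pB; pos <- hm_A$pos
    chrom <- hm_A$chrom
    wts <- if (!is.null(hm_A$weights)) hm_A$weights else rep(1, length(kA))
  }
  if (is.null(model)) {
    omega <- estimate_omega(kA / nA, pB)
    model <- xpclr_model(omega = max(omega, 1e-6))
  }
  prep <- .xpclr_prepare(kA, nA, pB, model)
  cm <- interpolate_cm(map, pos)

  starts <- seq(min(pos), max(pos), by = step_bp)
  out <- NULL
  for (sb in starts) {
    cm_start <- as.numeric(interpolate_cm(map, sb))
    cm_end <- cm_start + window_cm
    in_win <- which(cm >= cm_start & cm <= cm_end)
    if (length(in_win) < min_snps) next
    eb <- max(pos[in_win])
    cm_mid <- (cm_start + cm_end) / 2
    r <- abs(cm[in_win] - cm_mid) / 100          # Morgans
    w <- wts[in_win]
    ll0 <- sum(w * prep$logL0[in_win])
    best <- ll0
    s_hat <- 0
    for (s in model$s_grid) {
      cvec <- 1 - model$q0^(r / s)
      ll1 <- 0
      for (t in seq_along(in_win)) {
        L1 <- .xpclr_alt_lik(prep, in_win[t], cvec[t])
        if (L1 <= 0 || !is.finite(L1)) { ll1 <- -Inf; break }
        ll1 <- ll1 + w[t] * log(L1)
      }
      if (ll1 > best) { best <- ll1; s_hat <- s }
    }
    out <- rbind(out, data.frame(chrom = chrom, start_bp = sb,
                                 end_bp = eb,
                                 mid_bp = (sb + eb) / 2,
                                 cM_start = cm_start, cM_end = cm_end,
                                 n_snps = length(in_win),
                                 score = 2 * (best - ll0),
                                 s_hat = s_hat))
  }
  rownames(out) <- NULL
  out
}
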