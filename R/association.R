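#' Kruskal-Wallis rank test of group differences
#'
#' Thin wrapper around `stats::kruskal.test` (rank-based H with tie
#' correction, chi-square reference with groups - 1 df), with the
#' degenerate all-tied case returning H = 0, p = 1.
#'
#' @param values numeric outcome (e.g. hemoglobin in g/dl).
#' @param group_labels group membership, same length.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (length(unique(values)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Identity-by-state kinship matrix
#'
#' K_ij is the mean over pairwise-complete SNPs of
#' (2 - |dosage_i - dosage_j|) / 2, the IBS similarity EMMAX-style
#' mixed models use as the random-effect covariance.  If the smallest
#' eigenvalue is negative, (|lambda_min| + 1e-8) I is added to restore
#' positive semidefiniteness (attribute `stabilized`).
#'
#' @param gm a `genotype_matrix` with at least 100 SNPs.
#' @return Symmetric matrix of class `kinship_matrix`.
#' @export
ibs_kinship <- function(gm) {
  d <- gm$dosage
  if (ncol(d) < 100) stop("need at least 100 SNPs for kinship")
  n <- nrow(d)
  called <- !is.na(d)
  cnt <- tcrossprod(called * 1)
  if (any(cnt == 0)) stop("sample pair with zero shared called SNPs")
  # sum over SNPs of |d_i - d_j| via dosage-class indicator products
  A <- lapply(0:2, function(k) (called & d == k) * 1)
  S <- matrix(0, n, n)
  for (k in 0:2) for (l in 0:2) {
    if (k == l) next
    S <- S + abs(k - l) * tcrossprod(A[[k + 1]], A[[l + 1]])
  }
  K <- 1 - S / (2 * cnt)
  K <- (K + t(K)) / 2
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  stabilized <- FALSE
  if (lam_min < 0) {
    K <- K + diag(abs(lam_min) + 1e-8, n)
    stabilized <- TRUE
  }
  rownames(K) <- colnames(K) <- gm$samples$id
  structure(K, stabilized = stabilized,
            class = c("kinship_matrix", "matrix", "array"))
}

#' REML fit of the null mixed model (EMMA spectral approach)
#'
#' Fits y = X beta + u + e with Var(y) = sigma^2_g K + sigma^2_e I by a
#' single one-dimensional REML maximization over
#' delta = sigma^2_e / sigma^2_g, using the eigendecomposition of K to
#' diagonalize the covariance: a log-spaced delta grid on
#' \[1e-10, 1e10\] locates the mode and golden-section/parabolic
#' refinement (via `stats::optimize`) polishes it.  The rotation is
#' returned for reuse by every SNP test (the EMMAX approximation).
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (include the intercept; e.g.
#'   intercept, age, altitude).
#' @param K kinship matrix.
#' @return List of class `lmm_null`: `sigma2_g`, `sigma2_e`, `delta`,
#'   `pseudo_heritability`, `logREML`, `rotation` (U, xi), `X`, `y`,
#'   `converged`.
#' @export
lmm_fit_null <- function(y, X, K) {
  X <- as.matrix(X)
  n <- length(y)
  q <- ncol(X)
  if (n < q + 2) stop("too few samples for the model")
  if (qr(X)$rank < q) stop("collinear covariates")
  ev <- eigen(K, symmetric = TRUE)
  U <- ev$vectors
  xi <- pmax(ev$values, 0)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  reml <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (xi + delta)
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    0.5 * ((n - q) * (log((n - q) / (2 * pi)) - 1 - log(rss)) -
             sum(log(xi + delta)) -
             determinant(XtWX, logarithm = TRUE)$modulus + ldXX)
  }
  grid <- seq(-10, 10, length.out = 81)
  ll <- vapply(grid, reml, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
  converged <- TRUE
  if (opt$objective < ll[i]) {            # flat likelihood: keep grid max
    opt <- list(maximum = grid[i], objective = ll[i])
    converged <- FALSE
  }
  delta <- 10^opt$maximum
  w <- 1 / (xi + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  rss <- sum(w * (ys - Xs %*% beta)^2)
  sigma2_g <- rss / (n - q)
  sigma2_e <- delta * sigma2_g
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 delta = delta,
                 pseudo_heritability = 1 / (1 + delta),
                 logREML = opt$objective,
                 rotation = list(U = U, xi = xi),
                 X = X, y = y, beta = as.vector(beta),
                 converged = converged),
            class = "lmm_null")
}

#' Per-SNP mixed-model association (EMMAX approximation)
#'
#' Each SNP is tested by generalized least squares in the eigenrotated
#' space of the fitted null model, holding the variance-component ratio
#' delta fixed (the defining EMMAX approximation); the residual scale
#' is re-estimated per marker, so with K = I and no covariates the test
#' collapses exactly to ordinary least squares.  Dosages are
#' mean-imputed per SNP; SNPs with fewer than `min_genotype_classes`
#' distinct genotype classes among the tested samples are excluded
#' before testing.
#'
#' @param gm a `genotype_matrix` over the tested samples.
#' @param snp_subset SNP ids (or indices) to test, e.g. SNPs within
#'   100 kb of scan outliers.
#' @param null a fitted [lmm_fit_null()] on the same samples.
#' @param min_genotype_classes genotype classes required (default 3,
#'   i.e. SNPs with only two genotypes present are excluded; set to 2
#'   for the permissive reading).
#' @return Data frame of class `assoc_result`: `snp_id`, `beta`, `se`,
#'   `p_raw`, `p_bh`, `n`, `excluded` rows carry `NA` statistics.
#' @export
lmm_snp_assoc <- function(gm, snp_subset, null,
                          min_genotype_classes = 3) {
  idx <- if (is.character(snp_subset)) match(snp_subset, gm$snps$id) else
    snp_subset
  if (anyNA(idx)) stop("unknown SNP in snp_subset")
  U <- null$rotation$U
  xi <- null$rotation$xi
  w <- 1 / (xi + null$delta)
  ys <- crossprod(U, null$y)
  n <- length(null$y)

  res <- data.frame(snp_id = gm$snps$id[idx], beta = NA_real_,
                    se = NA_real_, p_raw = NA_real_, p_bh = NA_real_,
                    n = n, excluded = FALSE, stringsAsFactors = FALSE)
  for (t in seq_along(idx)) {
    d <- gm$dosage[, idx[t]]
    classes <- length(unique(d[!is.na(d)]))
    if (classes < min_genotype_classes) {
      res$excluded[t] <- TRUE
      next
    }
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    X <- cbind(null$X, snp = d)
    q <- ncol(X)
    if (qr(X)$rank < q) { res$excluded[t] <- TRUE; next }
    Xs <- crossprod(U, X)
    XtWX <- crossprod(Xs, Xs * w)
    XtWXi <- solve(XtWX)
    beta <- XtWXi %*% crossprod(Xs, ys * w)
    r <- ys - Xs %*% beta
    sigma2 <- sum(w * r^2) / (n - q)
    se <- sqrt(sigma2 * diag(XtWXi)[q])
    tstat <- beta[q] / se
    res$beta[t] <- beta[q]
    res$se[t] <- se
    res$p_raw[t] <- 2 * stats::pt(-abs(tstat), df = n - q)
  }
  tested <- !res$excluded
  res$p_bh[tested] <- bh_fdr(res$p_raw[tested])
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust`); input order is preserved.
#'
#' @param p_values raw p-values in (0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
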