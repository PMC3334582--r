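test_that("ld_r2 is the squared dosage correlation", {
  gm <- toy_gm(cbind(c(0, 1, 2, 0, 1, 2),
                     c(2, 1, 0, 2, 1, 0),
                     c(0, 0, 1, 1, 2, 2),
                     c(0, 1, 0, 1, 2, 2),
                     rep(1, 6)))
  expect_equal(ld_r2(gm, 1, 1), 1.0)
  expect_equal(ld_r2(gm, 1, 2), 1.0)        # perfect anti-correlation
  expect_equal(ld_r2(gm, 3, 4),
               cor(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 2, 2))^2)
  expect_warning(v <- ld_r2(gm, 1, 5), "zero")
  expect_true(is.na(v))
})

test_that("ld_prune removes exactly the over-threshold pairs", {
  # two perfectly correlated adjacent SNPs: one survives
  gm2 <- toy_gm(cbind(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2)))
  expect_length(ld_prune(gm2), 1)

  # mutually independent SNPs: all survive
  set.seed(1)
  gmi <- toy_gm(matrix(rbinom(40 * 8, 2, 0.5), 40, 8))
  r2max <- max(.Machine$double.eps, 0)
  kept <- ld_prune(gmi, r2_max = 0.5)
  expect_length(kept, 8)

  # planted correlation blocks: exhaustive post-check within windows
  set.seed(2)
  base <- matrix(rbinom(50 * 5, 2, 0.5), 50, 5)
  block <- base[, rep(1:5, each = 4)]      # 4 copies per block
  gmb <- toy_gm(block)
  kept <- ld_prune(gmb, window_snps = 20, step_snps = 5, r2_max = 0.5)
  ki <- match(kept, gmb$snps$id)
  sub <- gmb$dosage[, ki, drop = FALSE]
  r2 <- suppressWarnings(cor(sub))^2
  r2[lower.tri(r2, diag = TRUE)] <- 0
  expect_true(all(r2 <= 0.5))
  expect_identical(ld_prune(gmb, 20, 5, 0.5), kept)   # stable re-run
})

test_that("pca centers without scaling and matches an eigen oracle", {
  sim <- simulate_bn_genotypes(
    bn_sim_spec(n_snps = 50, pop_sizes = c(A = 5, B = 3, C = 2)),
    seed = 3)
  gm <- sim$gm
  gm$dosage[9:10, ] <- gm$dosage[1:2, ]    # duplicated samples
  pc <- pca(gm, 4)
  expect_equal(pc$coordinates[9, ], pc$coordinates[1, ],
               tolerance = 1e-10, ignore_attr = TRUE)

  # independent oracle: eigendecomposition of the sample covariance
  X <- gm$dosage
  storage.mode(X) <- "double"
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(tcrossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  oracle <- ev$vectors[, 1:4] %*% diag(sqrt(ev$values[1:4] * (nrow(X) - 1)))
  for (k in 1:4) {
    a <- pc$coordinates[, k]; b <- oracle[, k]
    if (sum(a * b) < 0) b <- -b
    expect_equal(a, b, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # total variance identity: sum of eigenvalues = trace of covariance
  expect_equal(sum(pc$eigenvalues), sum(diag(tcrossprod(Xc))) / (nrow(X) - 1),
               tolerance = 1e-8)
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_lte(sum(pc$variance_fraction), 1 + 1e-12)

  # two well-separated populations split on PC1
  sep <- 0
  for (s in 1:10) {
    g2 <- simulate_bn_genotypes(
      bn_sim_spec(n_snps = 400, pop_sizes = c(A = 15, B = 15, C = 2),
                  F_pop = c(A = 0.1, B = 0.1, C = 0.1)), seed = s)$gm
    p2 <- pca(g2, 2)
    a <- p2$coordinates[g2$samples$population == "A", 1]
    b <- p2$coordinates[g2$samples$population == "B", 1]
    if (max(a) < min(b) || max(b) < min(a)) sep <- sep + 1
  }
  expect_gte(sep, 9)
})

test_that("pihat matches the moment equations and pedigree expectations", {
  # equation-level oracle on a small cohort
  sim <- simulate_bn_genotypes(
    bn_sim_spec(n_snps = 120, pop_sizes = c(A = 3, B = 2, C = 2),
                F_pop = c(A = 0.01, B = 0.01, C = 0.01)), seed = 5)
  gm <- sim$gm
  ph <- pihat(gm)
  expect_true(isSymmetric(unclass(ph)))
  expect_equal(unname(diag(ph)), rep(1, 7))

  p <- allele_freqs(gm)
  oracle_pair <- function(i, j) {
    di <- gm$dosage[i, ]; dj <- gm$dosage[j, ]
    use <- !is.na(p) & p > 0 & p < 1 & !is.na(di) & !is.na(dj)
    pp <- p[use]; qq <- 1 - pp
    diffd <- abs(di[use] - dj[use])
    N <- c(sum(diffd == 2), sum(diffd == 1), sum(diffd == 0))
    e00 <- 2 * pp^2 * qq^2
    e10 <- 4 * pp^3 * qq + 4 * pp * qq^3
    e20 <- 1 - e00 - e10
    e11 <- 2 * pp^2 * qq + 2 * pp * qq^2
    e21 <- 1 - e11
    P0 <- N[1] / sum(e00)
    P1 <- (N[2] - P0 * sum(e10)) / sum(e11)
    P2 <- (N[3] - P0 * sum(e20) - P1 * sum(e21)) / sum(use)
    P <- pmax(c(P0, P1, P2), 0)
    if (sum(P) > 0) P <- P / sum(P)
    min(max(P[3] + P[2] / 2, 0), 1)
  }
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(ph[i, j], oracle_pair(i, j), tolerance = 1e-10)

  # duplicated sample: pi-hat near 1
  gm$dosage[2, ] <- gm$dosage[1, ]
  sim2 <- simulate_bn_genotypes(
    bn_sim_spec(n_snps = 5000, pop_sizes = c(A = 8, B = 2, C = 2),
                F_pop = c(A = 0.01, B = 0.01, C = 0.01)), seed = 6)
  gmd <- sim2$gm
  gmd$dosage[2, ] <- gmd$dosage[1, ]
  expect_gt(pihat(gmd)[1, 2], 0.9)

  # parent-offspring pairs center on 0.5
  vals <- numeric(25)
  for (s in 1:25) {
    g <- simulate_bn_genotypes(
      bn_sim_spec(n_snps = 2000, pop_sizes = c(A = 10, B = 2, C = 2),
                  F_pop = c(A = 0.01, B = 0.01, C = 0.01)),
      seed = s)$gm
    set.seed(s)
    pf <- allele_freqs(g)
    parent <- g$dosage[1, ]
    gamete <- ifelse(parent == 2, 1L,
                     ifelse(parent == 0, 0L,
                            rbinom(length(parent), 1, 0.5)))
    g$dosage[2, ] <- as.integer(gamete + rbinom(length(parent), 1, pf))
    vals[s] <- pihat(g)[1, 2]
  }
  expect_lt(abs(mean(vals) - 0.5), 0.1)
})

test_that("exclude_related removes a minimal over-threshold set", {
  mk <- function(mat) {
    rownames(mat) <- colnames(mat) <- sprintf("i%d", seq_len(nrow(mat)))
    structure(mat, class = c("relatedness_matrix", "matrix", "array"))
  }
  none <- mk(diag(4))
  expect_length(exclude_related(none), 0)

  one <- diag(4); one[1, 2] <- one[2, 1] <- 0.6
  expect_length(exclude_related(mk(one)), 1)

  # planted trio of mutual relatives vs exhaustive minimal removal
  tri <- diag(6)
  tri[1, 2] <- tri[2, 1] <- 0.5
  tri[1, 3] <- tri[3, 1] <- 0.5
  tri[2, 3] <- tri[3, 2] <- 0.5
  removed <- exclude_related(mk(tri))
  # exhaustive: smallest subset whose removal clears all related pairs
  best <- Inf
  for (k in 0:6) {
    combs <- utils::combn(6, k)
    for (ci in seq_len(ncol(combs))) {
      keep <- setdiff(1:6, combs[, ci])
      sub <- tri[keep, keep, drop = FALSE]
      diag(sub) <- 0
      if (all(sub <= 0.25)) { best <- min(best, k) }
    }
    if (is.finite(best)) break
  }
  expect_length(removed, best)
})
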