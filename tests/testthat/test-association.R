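test_that("kruskal_wallis matches hand ranks and rank-sum algebra", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3)),
               list(H = 0, p = 1))
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "two groups")

  # two groups: H equals the squared standardized rank-sum statistic
  vals <- c(3.1, 1.2, 5.5, 2.2, 4.4, 6.6, 0.5, 7.7, 8.1, 2.9)
  grp <- rep(c("x", "y"), each = 5)
  kw2 <- kruskal_wallis(vals, grp)
  r <- rank(vals)
  R1 <- sum(r[grp == "x"])
  n <- length(vals); n1 <- 5
  z <- (R1 - n1 * (n + 1) / 2) /
    sqrt(n1 * (n - n1) * (n + 1) / 12)
  expect_equal(kw2$H, z^2, tolerance = 1e-12)
})

test_that("ibs_kinship equals its definition and is stabilized", {
  sim <- simulate_bn_genotypes(
    bn_sim_spec(n_snps = 120, pop_sizes = c(A = 3, B = 2, C = 2)),
    seed = 4)
  gm <- sim$gm
  gm$dosage[2, ] <- gm$dosage[1, ]          # duplicate pair
  gm$dosage[3, ] <- 2L - gm$dosage[1, ]     # 0<->2 is distance 2... not all
  gm$dosage[4, 7] <- NA
  K <- ibs_kinship(gm)
  expect_equal(K[1, 2], 1)
  # direct double-loop recomputation
  for (i in 1:6) for (j in (i + 1):7) {
    di <- gm$dosage[i, ]; dj <- gm$dosage[j, ]
    ok <- !is.na(di) & !is.na(dj)
    expect_equal(K[i, j], mean((2 - abs(di[ok] - dj[ok])) / 2),
                 tolerance = 1e-12)
  }
  # opposite-homozygote pair scores 0
  gm2 <- gm
  gm2$dosage[1, ] <- 0L
  gm2$dosage[2, ] <- 2L
  expect_equal(ibs_kinship(gm2)[1, 2], 0)
  expect_error(ibs_kinship(gm_subset(gm, snps = 1:50)), "at least 100")
})

test_that("null REML collapses correctly and sits at a local optimum", {
  set.seed(11)
  n <- 60
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  null <- lmm_fit_null(y, X, diag(n))
  # K = I: total variance equals the OLS residual variance
  ols_var <- sum(stats::lm.fit(X, y)$residuals^2) / (n - 2)
  expect_equal(null$sigma2_g + null$sigma2_e, ols_var, tolerance = 1e-6)

  # optimum beats 20 random delta values
  sim <- simulate_bn_genotypes(
    bn_sim_spec(n_snps = 500, pop_sizes = c(A = 30, B = 20, C = 10)),
    seed = 3)
  K <- unclass(ibs_kinship(sim$gm))
  ph <- simulate_phenotypes(sim$gm, K = K, seed = 5)$phenotypes
  Xp <- cbind(1, ph$age, ph$altitude_m)
  fit <- lmm_fit_null(ph$hemoglobin_gdl, Xp, K)
  ev <- eigen(K, symmetric = TRUE)
  reml_at <- function(delta) {
    xi <- pmax(ev$values, 0); U <- ev$vectors
    ys <- crossprod(U, ph$hemoglobin_gdl); Xs <- crossprod(U, Xp)
    w <- 1 / (xi + delta)
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    rss <- sum(w * (ys - Xs %*% beta)^2)
    nq <- length(ys) - ncol(Xp)
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(rss)) -
             sum(log(xi + delta)) -
             determinant(XtWX, logarithm = TRUE)$modulus +
             determinant(crossprod(Xp), logarithm = TRUE)$modulus)
  }
  set.seed(1)
  for (d in 10^runif(20, -6, 6))
    expect_gte(fit$logREML + 1e-6, as.numeric(reml_at(d)))
  expect_error(lmm_fit_null(y, cbind(X, X[, 2]), diag(n)), "collinear")
})

test_that("EMMAX SNP tests collapse to OLS and exclude 2-class SNPs", {
  set.seed(21)
  n <- 50
  sim <- simulate_bn_genotypes(
    bn_sim_spec(n_snps = 150, pop_sizes = c(A = 30, B = 10, C = 10)),
    seed = 8)
  gm <- sim$gm
  y <- rnorm(n)
  null <- lmm_fit_null(y, matrix(1, n, 1), diag(n))
  res <- lmm_snp_assoc(gm, 1:30, null)
  for (t in which(!res$excluded)[1:5]) {
    d <- gm$dosage[, t]
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    ols <- summary(stats::lm(y ~ d))$coefficients
    expect_equal(res$beta[t], ols[2, 1], tolerance = 1e-8)
    expect_equal(res$p_raw[t], ols[2, 4], tolerance = 1e-8)
  }

  # SNPs with only two genotype classes are excluded before testing
  gm$dosage[, 3] <- rep(c(0L, 1L), length.out = n)
  res2 <- lmm_snp_assoc(gm, 1:5, null)
  expect_true(res2$excluded[3])
  expect_true(is.na(res2$p_raw[3]))
  res3 <- lmm_snp_assoc(gm, 1:5, null, min_genotype_classes = 2)
  expect_false(res3$excluded[3])

  # association p-values do not depend on sample order
  ord <- sample(n)
  gm_o <- gm_subset(gm, samples = ord)
  null_o <- lmm_fit_null(y[ord], matrix(1, n, 1), diag(n))
  res_o <- lmm_snp_assoc(gm_o, 1:30, null_o)
  expect_equal(res_o$p_raw, res$p_raw, tolerance = 1e-9)
})

test_that("planted causal SNPs rank first in their region", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_bn_genotypes(
      bn_sim_spec(n_snps = 150, pop_sizes = c(A = 50, B = 48, C = 2)),
      seed = s)
    gm <- gm_subset(sim$gm, samples = sim$gm$samples$population != "C")
    causal <- gm$snps$id[75]
    sp <- pheno_sim_spec(causal_snp = causal, causal_snp_effect = 1,
                         polygenic_var = 0, residual_var = 0.5)
    ph <- simulate_phenotypes(gm, spec = sp, seed = s)$phenotypes
    X <- cbind(1, ph$age, ph$altitude_m)
    null <- lmm_fit_null(ph$hemoglobin_gdl, X,
                         unclass(ibs_kinship(gm)))
    res <- lmm_snp_assoc(gm, seq_len(150), null)
    if (!is.na(res$p_raw[75]) &&
        res$p_raw[75] == min(res$p_raw, na.rm = TRUE)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("bh_fdr reproduces the step-up adjustment", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
})
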