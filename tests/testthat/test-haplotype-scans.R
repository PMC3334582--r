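test_that("polarize applies the unambiguous-outgroup rule", {
  hm <- toy_hm(matrix(c(0L, 1L), 2, 3), polarized = FALSE)
  og <- data.frame(snp_id = c("s001", "s002", "s003"),
                   chimp = c("A", "A", "C"),
                   orang = c("A", "G", NA),
                   macaque = c(NA, NA, NA),
                   stringsAsFactors = FALSE)
  # s001: agreement on a segregating allele -> ancestral A (allele0)
  # s002: covered outgroups conflict -> removed
  # s003: non-segregating base -> removed
  pol <- polarize(hm, og)
  expect_equal(pol$removed, c("s002", "s003"))
  expect_equal(ncol(pol$hm$alleles), 1)
  expect_equal(unname(pol$hm$alleles[, 1]), c(0L, 1L))   # unflipped

  # ancestral = allele1 flips the column
  og2 <- data.frame(snp_id = "s001", chimp = "G", orang = "G",
                    macaque = "G", stringsAsFactors = FALSE)
  pol2 <- polarize(toy_hm(matrix(c(0L, 1L), 2, 1), polarized = FALSE),
                   og2)
  expect_equal(unname(pol2$hm$alleles[, 1]), c(1L, 0L))
  expect_equal(pol2$hm$snps$allele0[1], "G")
  expect_error(polarize(hm, og[0, ]), "empty")
})

test_that("maf_filter drops SNPs rare in either population", {
  # columns: (4%, 20%), (5%, 5%), (50%, 50%), (0%, 30%)
  nA <- 100; nB <- 40
  mkcol <- function(ka, kb) c(rep(1L, ka), rep(0L, nA - ka),
                              rep(1L, kb), rep(0L, nB - kb))
  al <- cbind(mkcol(4, 8), mkcol(5, 2), mkcol(50, 20), mkcol(0, 12))
  hm <- toy_hm(al, populations = rep(c("A", "B"), c(nA, nB)))
  out <- maf_filter(hm, 0.05, c("A", "B"))
  expect_equal(attr(out, "snps_removed"), c("s001", "s004"))
  expect_equal(out$snps$id, c("s002", "s003"))
  expect_error(maf_filter(hm, populations = "Z"), "unknown population")

  # planted 100-SNP toy agrees with a direct hand count
  set.seed(3)
  f <- runif(100, 0, 0.5)
  alleles <- sapply(f, function(p) rbinom(nA + nB, 1, p))
  hm2 <- toy_hm(alleles, populations = rep(c("A", "B"), c(nA, nB)))
  out2 <- maf_filter(hm2, 0.05, c("A", "B"))
  fa <- colMeans(alleles[1:nA, ]); fb <- colMeans(alleles[-(1:nA), ])
  keep <- pmin(fa, 1 - fa) >= 0.05 & pmin(fb, 1 - fb) >= 0.05
  expect_equal(ncol(out2$alleles), sum(keep))
})

test_that("ehh equals the brute-force prefix enumeration", {
  # 8 haplotypes x 6 SNPs, written out
  al <- rbind(c(1, 1, 1, 1, 0, 1),
              c(0, 1, 1, 1, 0, 1),
              c(1, 0, 1, 1, 1, 1),
              c(0, 0, 1, 1, 1, 0),
              c(1, 1, 0, 1, 0, 0),
              c(0, 1, 0, 0, 1, 1),
              c(1, 0, 0, 0, 1, 0),
              c(0, 1, 1, 0, 0, 1))
  hm <- toy_hm(al)
  core <- 3
  carriers <- which(al[, core] == 1)
  crv <- ehh(hm, core, "derived", ehh_min = 0, max_gap_bp = 1e9)
  expect_equal(crv$left$ehh[1], 1)
  for (k in seq_along(crv$right$ehh))
    expect_equal(crv$right$ehh[k],
                 ehh_oracle(al, carriers, core, core + k - 1))
  for (k in seq_along(crv$left$ehh))
    expect_equal(crv$left$ehh[k],
                 ehh_oracle(al, carriers, core, core - k + 1))

  # 4 carriers splitting into two identical pairs: EHH = 1/3
  al2 <- rbind(c(1, 0), c(1, 0), c(1, 1), c(1, 1),
               c(0, 0), c(0, 0), c(0, 1), c(0, 1))
  crv2 <- ehh(toy_hm(al2), 1, "derived", ehh_min = 0)
  expect_equal(crv2$right$ehh[2], 1 / 3)
  expect_error(ehh(toy_hm(rbind(c(1, 0), c(0, 0))), 1, "derived"),
               "fewer than 2 carriers")
})

test_that("unstandardized iHS integrates EHH and keeps its sign convention", {
  # mirror-image allele classes whose EHH reaches 0 inside the region:
  # score exactly 0
  al <- rbind(c(0, 0, 1, 0, 0),
              c(0, 1, 1, 1, 0),
              c(1, 0, 1, 0, 1),
              c(1, 1, 1, 1, 1),
              c(0, 0, 0, 0, 0),
              c(0, 1, 0, 1, 0),
              c(1, 0, 0, 0, 1),
              c(1, 1, 0, 1, 1))
  hm <- toy_hm(al, pos = (1:5) * 1e5,
               map = genetic_map(c(0, 1e6), c(0, 1)))
  v <- ihs_unstandardized(hm, 3)
  expect_equal(as.numeric(v), 0)

  # written-out 6 x 7 toy: EHH sequences are (1, 1/3, 0) per side for
  # the ancestral class and an extra 1/3 plateau on the derived right
  # side; uniform 1 cM/Mb map, 0.1 cM per SNP step
  al3 <- rbind(c(1, 1, 1, 1, 1, 1, 1),
               c(0, 0, 1, 1, 1, 1, 0),
               c(0, 1, 0, 1, 0, 0, 1),
               c(1, 1, 1, 0, 1, 1, 0),
               c(0, 0, 1, 0, 1, 0, 1),
               c(1, 1, 0, 0, 0, 1, 1))
  hm3 <- toy_hm(al3, pos = (1:7) * 1e5,
                map = genetic_map(c(0, 1e6), c(0, 1)))
  vv <- ihs_unstandardized(hm3, 4)
  ihh_d_hand <- 0.1 * (1 + 1 / 3) / 2 + 0.1 * (1 / 3) / 2 +   # left
    0.1 * (1 + 1 / 3) / 2 + 0.1 * (1 / 3 + 1 / 3) / 2 +
    0.1 * (1 / 3) / 2                                         # right
  ihh_a_hand <- 2 * (0.1 * (1 + 1 / 3) / 2 + 0.1 * (1 / 3) / 2)
  expect_equal(as.numeric(vv), log(ihh_a_hand / ihh_d_hand),
               tolerance = 1e-12)
  expect_equal(attr(vv, "ihh_a"), ihh_a_hand, tolerance = 1e-12)
  expect_equal(attr(vv, "ihh_d"), ihh_d_hand, tolerance = 1e-12)

  # sweeps make derived haplotypes long: raw iHS negative at the focal SNP
  neg <- 0; n_def <- 0
  for (s in 1:10) {
    sw <- simulate_sweep_haplotypes(seed = s)
    hmA <- hm_subset_pop(sw$hm, "A")
    v <- ihs_unstandardized(hmA, sw$truth$focal_index)
    if (!is.na(v)) {
      n_def <- n_def + 1
      if (as.numeric(v) < 0) neg <- neg + 1
    }
  }
  expect_gte(neg / n_def, 0.9)
})

test_that("iHS standardization is exact within bins and de-trends", {
  out <- ihs_standardize(c(-1, 1), c(0.5, 0.5), n_bins = 1,
                         min_per_bin = 2)
  expect_equal(out$ihs, c(-1, 1))

  set.seed(7)
  freqs <- runif(5000, 0.05, 0.95)
  scores <- -2 * freqs + rnorm(5000)       # frequency-dependent drift
  std <- ihs_standardize(scores, freqs)
  for (b in unique(std$bin)) {
    x <- std$ihs[std$bin == b]
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(mean((x - mean(x))^2) - 1), 1e-10)
  }
  slope <- coef(lm(std$ihs ~ freqs))[2]
  expect_lt(abs(slope), 0.05)

  # undefined scores pass through as NA
  s2 <- ihs_standardize(c(NA, rnorm(40)), runif(41, 0.2, 0.3),
                        n_bins = 2)
  expect_true(is.na(s2$ihs[1]))
  expect_equal(sum(is.na(s2$ihs)), 1)
})

test_that("iHS pipeline is deterministic and neutral tails are normal-like", {
  sw <- simulate_sweep_haplotypes(seed = 12)
  hmB <- maf_filter(hm_subset_pop(sw$hm, "B"), 0.05)
  run <- function() {
    sc <- ihs_scan(hmB)
    ihs_standardize(sc$raw, sc$derived_freq)$ihs
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
  # neutral background: |iHS| > 2 fraction within the normal-tail band
  fr <- mean(abs(r1) > 2, na.rm = TRUE)
  expect_gte(fr, 0.005)
  expect_lte(fr, 0.10)
})

test_that("core haplotype frequencies tally phased cores per population", {
  al <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 0),
              c(0, 1, 1), c(0, 1, 1), c(0, 1, 1))
  hm <- toy_hm(al, populations = rep(c("A", "B"), each = 3))
  chf <- core_haplotype_freq(hm, 1:3)
  a <- chf[chf$population == "A", ]
  expect_equal(sort(a$freq, decreasing = TRUE), c(2 / 3, 1 / 3))
  expect_equal(a$freq[a$haplotype == "110"], 2 / 3)
  b <- chf[chf$population == "B", ]
  expect_equal(b$haplotype, "011")
  expect_equal(b$freq, 1)

  # all identical cores
  hm1 <- toy_hm(matrix(1L, 6, 3), populations = rep(c("A", "B"), 3))
  chf1 <- core_haplotype_freq(hm1, 1:3)
  expect_true(all(chf1$freq == 1))

  # missing core alleles drop out of the denominator
  alm <- al; alm[1, 2] <- NA
  chfm <- core_haplotype_freq(toy_hm(alm,
                                     populations = rep(c("A", "B"),
                                                       each = 3)), 1:3)
  am <- chfm[chfm$population == "A", ]
  expect_equal(sum(am$count), 2)
  expect_equal(sum(am$freq), 1)
  expect_error(core_haplotype_freq(hm, c("nope", "s001", "s002")),
               "not covered")
})

test_that("sweep cores recover the planted population contrast", {
  ok_A <- ok_B <- 0
  for (s in 1:8) {
    sw <- simulate_sweep_haplotypes(seed = s)
    core_idx <- sw$truth$focal_index + (-1:1)
    chf <- core_haplotype_freq(sw$hm, core_idx)
    a <- chf[chf$population == "A", ]
    dom <- a$haplotype[which.max(a$freq)]
    fB <- chf$freq[chf$population == "B" & chf$haplotype == dom]
    if (abs(max(a$freq) - 0.482) <= 0.05) ok_A <- ok_A + 1
    if (length(fB) == 0 || fB < 0.10) ok_B <- ok_B + 1
  }
  expect_gte(ok_A, 6)
  expect_gte(ok_B, 7)
})
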