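test_that("Balding-Nichols generator matches its drift estimand", {
  # no-drift limit: population frequencies collapse onto the ancestral
  spec0 <- bn_sim_spec(n_snps = 20000, pop_sizes = c(A = 30, B = 30, C = 2),
                       F_pop = c(A = 1e-6, B = 1e-6, C = 1e-6))
  sim0 <- simulate_bn_genotypes(spec0, seed = 11)
  f0 <- wc_fst_scan(sim0$gm, "A", "B")
  expect_lt(abs(mean(f0, na.rm = TRUE)), 0.005)

  # mean per-SNP frequency tracks the ancestral p
  fA <- allele_freqs(sim0$gm, sim0$gm$samples$population == "A")
  expect_lt(abs(mean(fA - sim0$ancestral_freq)), 0.01)

  # determinism
  s1 <- simulate_bn_genotypes(bn_sim_spec(n_snps = 100), seed = 5)
  s2 <- simulate_bn_genotypes(bn_sim_spec(n_snps = 100), seed = 5)
  expect_identical(s1$gm$dosage, s2$gm$dosage)
  s3 <- simulate_bn_genotypes(bn_sim_spec(n_snps = 100), seed = 6)
  expect_false(identical(s1$gm$dosage, s3$gm$dosage))
})

test_that("sweep generator reaches its target frequencies and limits", {
  spec <- sweep_sim_spec()
  sim <- simulate_sweep_haplotypes(spec, seed = 3)
  fA <- hm_freq(hm_subset_pop(sim$hm, "A"))[sim$truth$focal_index]
  fB <- hm_freq(hm_subset_pop(sim$hm, "B"))[sim$truth$focal_index]
  expect_lt(abs(fA - spec$target_freq_A), 1 / spec$n_haplotypes[["A"]])
  expect_lt(abs(fB - spec$target_freq_B), 1 / spec$n_haplotypes[["B"]])

  # zero breakpoint rate: all focal-population carriers identical
  spec0 <- sweep_sim_spec(recomb_rate_cM_per_Mb = 0, n_snps = 100)
  sim0 <- simulate_sweep_haplotypes(spec0, seed = 4)
  carr <- sim0$truth$carriers_A
  expect_true(all(apply(sim0$hm$alleles[carr, , drop = FALSE], 2,
                        function(x) length(unique(x)) == 1)))
  # with identical carriers, derived-core EHH is 1 at every offset
  crv <- ehh(sim0$hm, sim0$truth$focal_index, "derived",
             population = "A")
  expect_true(all(crv$left$ehh == 1))
  expect_true(all(crv$right$ehh == 1))
})

test_that("outgroup tables encode the planned ambiguity rate", {
  sim <- simulate_bn_genotypes(bn_sim_spec(n_snps = 10000,
                                           pop_sizes = c(A = 4, B = 3,
                                                         C = 3)),
                               seed = 8)
  # haplotype view of the genotypes for polarization
  og <- simulate_outgroup_alleles(sim$gm, ambiguous_fraction = 0.05,
                                  seed = 9)
  expect_lt(abs(mean(og$truth$ambiguous) - 0.05), 0.01)

  hm <- toy_hm(matrix(rep(c(0L, 1L), 10000), nrow = 2),
               pos = sim$gm$snps$pos)
  hm$snps$id <- sim$gm$snps$id
  pol <- polarize(hm, og$outgroups)
  expect_setequal(pol$removed, og$truth$snp_id[og$truth$ambiguous])

  og0 <- simulate_outgroup_alleles(sim$gm, ambiguous_fraction = 0,
                                   seed = 9)
  pol0 <- polarize(hm, og0$outgroups)
  expect_length(pol0$removed, 0)
})

test_that("phenotype generator honours its variance and effect structure", {
  gm <- simulate_bn_genotypes(bn_sim_spec(n_snps = 200,
                                          pop_sizes = c(A = 28, B = 8,
                                                        C = 7)),
                              seed = 1)$gm
  # noise-free: within-population hemoglobin exactly constant
  sp0 <- pheno_sim_spec(polygenic_var = 0, residual_var = 0)
  ph0 <- simulate_phenotypes(gm, spec = sp0, seed = 2)$phenotypes
  for (p in c("A", "B", "C"))
    expect_equal(stats::sd(ph0$hemoglobin_gdl[ph0$population == p]), 0)

  # doubling the residual variance doubles the noise moment
  v1 <- v2 <- numeric(50)
  for (s in 1:50) {
    p1 <- simulate_phenotypes(gm, spec = pheno_sim_spec(
      polygenic_var = 0, residual_var = 1), seed = s)$phenotypes
    p2 <- simulate_phenotypes(gm, spec = pheno_sim_spec(
      polygenic_var = 0, residual_var = 2), seed = s + 1000)$phenotypes
    a <- p1$hemoglobin_gdl[p1$population == "A"]
    b <- p2$hemoglobin_gdl[p2$population == "A"]
    v1[s] <- stats::var(a); v2[s] <- stats::var(b)
  }
  expect_lt(abs(mean(v2) / mean(v1) - 2), 0.4)
})

test_that("simulated genetic maps are monotone with the nominal rate", {
  m0 <- simulate_genetic_map(1e6, 1, jitter = 0, seed = 1)
  expect_equal(max(m0$pos_cM), 1.0)
  mj <- simulate_genetic_map(1e6, 1, jitter = 0.5, seed = 2,
                             n_intervals = 100)
  expect_true(all(diff(mj$pos_bp) > 0))
  expect_true(all(diff(mj$pos_cM) >= 0))
  rate <- max(mj$pos_cM) / (max(mj$pos_bp) - min(mj$pos_bp)) * 1e6
  expect_lt(abs(rate - 1) / 1, 0.1)
})
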