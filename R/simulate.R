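#' Specification for Balding-Nichols genotype simulation
#'
#' Three populations mirroring the study design: a focal high-altitude
#' population (A), a low-altitude neighbour (B) and a distant reference
#' (C).  Default sample sizes follow the study cohort (27 unrelated
#' high-altitude, 19 low-altitude, 113 reference individuals); default
#' drift coefficients give the modest differentiation expected among
#' African populations.
#'
#' @param n_snps number of SNPs.
#' @param pop_sizes named diploid sample sizes for populations A, B, C.
#' @param F_pop named Balding-Nichols drift parameters per population.
#' @param ancestral_freq_range interval the ancestral frequency is drawn
#'   from, uniformly.
#' @param n_outlier_snps number of planted population-A outlier SNPs.
#' @param outlier_target_freq_A population-A allele frequency forced at
#'   outlier SNPs (B and C stay at the ancestral frequency).
#' @param chrom chromosome label for the emitted SNPs.
#' @return List of class `bn_sim_spec`.
#' @export
bn_sim_spec <- function(n_snps = 5000,
                        pop_sizes = c(A = 27, B = 19, C = 113),
                        F_pop = c(A = 0.05, B = 0.05, C = 0.05),
                        ancestral_freq_range = c(0.05, 0.95),
                        n_outlier_snps = 0,
                        outlier_target_freq_A = 0.9,
                        chrom = "1") {
  stopifnot(all(F_pop > 0), all(F_pop < 1), all(pop_sizes >= 2),
            n_outlier_snps <= n_snps,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1)
  structure(list(n_snps = n_snps, pop_sizes = pop_sizes, F_pop = F_pop,
                 ancestral_freq_range = ancestral_freq_range,
                 n_outlier_snps = n_outlier_snps,
                 outlier_target_freq_A = outlier_target_freq_A,
                 chrom = chrom),
            class = "bn_sim_spec")
}

#' Simulate three-population Balding-Nichols genotypes
#'
#' Per SNP an ancestral frequency p is drawn uniformly from the spec
#' range; each population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F)
#' and genotypes are Binomial(2, population frequency).  Planted outlier
#' SNPs instead force the population-A frequency to the spec target
#' while B and C sit at the ancestral frequency, emulating a
#' focal-population-specific frequency shift.
#'
#' @param spec a [bn_sim_spec()].
#' @param seed integer seed; the run is bit-reproducible given
#'   (spec, seed).
#' @return List with `gm` (a `genotype_matrix`), `truth` (data frame of
#'   planted outlier SNP ids) and `ancestral_freq` (per-SNP p).
#' @export
simulate_bn_genotypes <- function(spec = bn_sim_spec(), seed = 1) {
  set.seed(seed)
  m <- spec$n_snps
  pops <- names(spec$pop_sizes)
  p <- stats::runif(m, spec$ancestral_freq_range[1],
                    spec$ancestral_freq_range[2])
  outlier_idx <- if (spec$n_outlier_snps > 0)
    sort(sample.int(m, spec$n_outlier_snps)) else integer(0)
  # planted outliers carry a genuine focal-branch shift: their shared
  # B/C (ancestral) frequency sits in the lower half of the range so the
  # forced population-A frequency is a real contrast
  if (length(outlier_idx) > 0)
    p[outlier_idx] <- stats::runif(length(outlier_idx),
                                   spec$ancestral_freq_range[1],
                                   min(0.5, spec$ancestral_freq_range[2]))

  freq <- matrix(NA_real_, m, length(pops), dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    F <- spec$F_pop[[pops[k]]]
    shape_scale <- (1 - F) / F
    freq[, k] <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)
  }
  if (length(outlier_idx) > 0) {
    freq[outlier_idx, "A"] <- spec$outlier_target_freq_A
    freq[outlier_idx, "B"] <- p[outlier_idx]
    freq[outlier_idx, "C"] <- p[outlier_idx]
  }

  n_total <- sum(spec$pop_sizes)
  dos <- matrix(NA_integer_, n_total, m)
  pop_label <- rep(pops, spec$pop_sizes)
  for (k in seq_along(pops)) {
    rows <- which(pop_label == pops[k])
    dos[rows, ] <- stats::rbinom(length(rows) * m, 2,
                                 rep(freq[, k], each = length(rows)))
  }

  # ~3 kb mean spacing, the density of a 1M-SNP genotyping array
  pos <- sort(sample.int(3000 * m, m))
  snp_id <- sprintf("snp%05d", seq_len(m))
  snps <- data.frame(id = snp_id, chrom = spec$chrom, pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("%s%03d", pop_label,
                                     unlist(lapply(spec$pop_sizes, seq_len))),
                        population = pop_label, stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, snps, samples)
  list(gm = gm,
       truth = data.frame(snp_id = snp_id[outlier_idx],
                          stringsAsFactors = FALSE),
       ancestral_freq = p)
}

#' Specification for sweep-structured haplotype simulation
#'
#' Emulates an incomplete selective sweep: a focal derived allele at
#' high frequency in the focal population riding a single long shared
#' haplotype, present at low frequency without the long haplotype in
#' the comparison population.  Default focal frequencies follow the
#' candidate core-haplotype contrast reported for the study region
#' (0.482 in the high-altitude sample vs 0.026 at low altitude).  The
#' default region (3 Mb) is much longer than the swept segment
#' (mean shared flank ~170 kb per side) so that, as in a genome-wide
#' scan, frequency-bin standardization of iHS is referenced against a
#' predominantly neutral background rather than the sweep itself.
#'
#' @param n_haplotypes named haplotype counts per population (must be
#'   even; two per diploid sample).
#' @param n_snps SNPs in the region.
#' @param region_length_bp physical length of the region.
#' @param focal_index index of the swept SNP (default: middle of the
#'   region).
#' @param target_freq_A derived-allele frequency of the focal SNP in
#'   population A.
#' @param target_freq_B same, population B.
#' @param recomb_rate_cM_per_Mb mean recombination rate.
#' @param mosaic_switch_rate per-SNP founder-switch probability of the
#'   neutral mosaic backbone.
#' @param n_founders founder-panel size for the mosaic.
#' @param sweep_time_gen effective hitchhiking duration in generations;
#'   together with the recombination rate it sets the per-bp breakpoint
#'   rate of the swept haplotype (mean shared flank =
#'   1 / (rate_per_bp * sweep_time_gen)).
#' @param map_jitter log-normal jitter of the per-interval map rate.
#' @param chrom chromosome label.
#' @return List of class `sweep_sim_spec`.
#' @export
sweep_sim_spec <- function(n_haplotypes = c(A = 100, B = 100),
                           n_snps = 900,
                           region_length_bp = 3e6,
                           focal_index = NULL,
                           target_freq_A = 0.482,
                           target_freq_B = 0.026,
                           recomb_rate_cM_per_Mb = 1,
                           mosaic_switch_rate = 0.1,
                           n_founders = 20,
                           sweep_time_gen = 600,
                           map_jitter = 0.2,
                           chrom = "1") {
  if (is.null(focal_index)) focal_index <- n_snps %/% 2
  stopifnot(target_freq_A > 0, target_freq_A < 1,
            target_freq_B > 0, target_freq_B < 1,
            focal_index > 1, focal_index < n_snps,
            all(n_haplotypes %% 2 == 0))
  structure(list(n_haplotypes = n_haplotypes, n_snps = n_snps,
                 region_length_bp = region_length_bp,
                 focal_index = focal_index,
                 target_freq_A = target_freq_A,
                 target_freq_B = target_freq_B,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 mosaic_switch_rate = mosaic_switch_rate,
                 n_founders = n_founders,
                 sweep_time_gen = sweep_time_gen,
                 map_jitter = map_jitter, chrom = chrom),
            class = "sweep_sim_spec")
}

#' Simulate sweep-structured phased haplotypes
#'
#' Neutral backbone haplotypes are mosaics of a founder panel (per-SNP
#' switch probability `mosaic_switch_rate`).  The sweep is imposed in
#' population A by sampling carriers up to the target frequency and
#' replacing each carrier's sequence around the focal SNP with a copy of
#' one template haplotype, out to an exponentially distributed
#' recombination breakpoint on each side (per-bp rate = recombination
#' rate in Morgans/bp times `sweep_time_gen`), which produces the
#' extended-haplotype-homozygosity decay a partial sweep leaves.
#' Population B receives its carriers without haplotype replacement.
#'
#' @param spec a [sweep_sim_spec()].
#' @param seed integer seed.
#' @return List with `hm` (polarized `haplotype_matrix` with companion
#'   map), `map`, and `truth` (focal SNP id/index, carrier haplotype
#'   rows).
#' @export
simulate_sweep_haplotypes <- function(spec = sweep_sim_spec(), seed = 1) {
  set.seed(seed)
  m <- spec$n_snps
  len <- spec$region_length_bp
  pos <- sort(sample.int(len - 2, m)) + 1L
  map <- if (spec$recomb_rate_cM_per_Mb > 0)
    simulate_genetic_map(len, spec$recomb_rate_cM_per_Mb,
                         jitter = spec$map_jitter,
                         seed = seed + 77777L)
  else genetic_map(c(1, len + 1), c(0, 0))       # fully linked region

  # founder panel: per-SNP frequencies then independent founder alleles
  pf <- stats::runif(m, 0.1, 0.9)
  founders <- matrix(stats::rbinom(spec$n_founders * m, 1,
                                   rep(pf, each = spec$n_founders)),
                     spec$n_founders, m)
  founders[, spec$focal_index] <- 0L          # focal derived arises once

  n_hap <- sum(spec$n_haplotypes)
  pops <- rep(names(spec$n_haplotypes), spec$n_haplotypes)
  alleles <- matrix(0L, n_hap, m)
  for (i in seq_len(n_hap)) {
    sw <- stats::runif(m) < spec$mosaic_switch_rate
    sw[1] <- TRUE
    src <- sample.int(spec$n_founders, sum(sw), replace = TRUE)
    idx <- cumsum(sw)
    alleles[i, ] <- founders[cbind(src[idx], seq_len(m))]
  }

  rows_A <- which(pops == "A")
  rows_B <- which(pops == "B")
  n_carr_A <- round(spec$target_freq_A * length(rows_A))
  n_carr_B <- round(spec$target_freq_B * length(rows_B))
  carriers_A <- sample(rows_A, n_carr_A)
  carriers_B <- sample(rows_B, n_carr_B)

  template <- alleles[carriers_A[1], ]
  template[spec$focal_index] <- 1L
  rate_bp <- spec$recomb_rate_cM_per_Mb / 100 / 1e6 * spec$sweep_time_gen
  focal_pos <- pos[spec$focal_index]
  for (i in carriers_A) {
    if (rate_bp > 0) {
      dl <- stats::rexp(1, rate_bp)
      dr <- stats::rexp(1, rate_bp)
    } else {
      dl <- dr <- Inf
    }
    seg <- pos >= focal_pos - dl & pos <= focal_pos + dr
    alleles[i, seg] <- template[seg]
    alleles[i, spec$focal_index] <- 1L
  }
  alleles[carriers_B, spec$focal_index] <- 1L

  snp_id <- sprintf("snp%05d", seq_len(m))
  snps <- data.frame(id = snp_id, chrom = spec$chrom, pos = pos,
                     allele0 = "A", allele1 = "G",
                     stringsAsFactors = FALSE)
  sample_id <- paste0(rep(pops[seq(1, n_hap, 2)], each = 2),
                      rep(sprintf("%03d", seq_len(n_hap / 2)), each = 2))
  hm <- haplotype_matrix(alleles, snps, sample_id, pops, map,
                         polarized = TRUE)
  list(hm = hm, map = map,
       truth = list(focal_snp = snp_id[spec$focal_index],
                    focal_index = spec$focal_index,
                    focal_pos = pos[spec$focal_index],
                    carriers_A = sort(carriers_A),
                    carriers_B = sort(carriers_B)))
}

#' Simulate an outgroup allele table with planted ambiguity
#'
#' For `1 - ambiguous_fraction` of SNPs the three outgroups (priority
#' order chimp > orang > macaque) all carry the truth ancestral allele;
#' the remaining SNPs are made unusable for polarization by planting an
#' outgroup conflict, a non-segregating base, or total missingness.
#'
#' @param snps SNP data frame with `id` plus allele columns (`ref`/`alt`
#'   or `allele0`/`allele1`); a `genotype_matrix` or `haplotype_matrix`
#'   is also accepted.
#' @param ambiguous_fraction fraction of SNPs rendered ambiguous
#'   (default 0.05, the study's reported loss).
#' @param seed integer seed.
#' @return List with `outgroups` (data frame: snp_id, chimp, orang,
#'   macaque) and `truth` (snp_id, ancestral allele, ambiguous flag).
#' @export
simulate_outgroup_alleles <- function(snps, ambiguous_fraction = 0.05,
                                      seed = 1) {
  set.seed(seed)
  if (inherits(snps, "genotype_matrix") ||
      inherits(snps, "haplotype_matrix")) snps <- snps$snps
  a0 <- if (!is.null(snps$allele0)) snps$allele0 else snps$ref
  a1 <- if (!is.null(snps$allele1)) snps$allele1 else snps$alt
  m <- nrow(snps)
  # truth ancestral: the 0-coded/ref allele for polarized input, random
  # otherwise would complicate truth bookkeeping -- keep it the 0 allele
  ancestral <- a0
  derived <- a1
  amb <- stats::runif(m) < ambiguous_fraction
  chimp <- orang <- macaque <- ancestral
  mode <- sample(1:3, m, replace = TRUE)
  for (j in which(amb)) {
    if (mode[j] == 1) {          # conflict between covered outgroups
      orang[j] <- derived[j]
    } else if (mode[j] == 2) {   # non-segregating base in all outgroups
      other <- setdiff(c("A", "C", "G", "T"), c(ancestral[j], derived[j]))
      chimp[j] <- orang[j] <- macaque[j] <- other[1]
    } else {                     # fully missing
      chimp[j] <- orang[j] <- macaque[j] <- NA_character_
    }
  }
  list(outgroups = data.frame(snp_id = snps$id, chimp = chimp,
                              orang = orang, macaque = macaque,
                              stringsAsFactors = FALSE),
       truth = data.frame(snp_id = snps$id, ancestral = ancestral,
                          ambiguous = amb, stringsAsFactors = FALSE))
}

#' Specification for hemoglobin phenotype simulation
#'
#' Defaults reproduce the study's field measurements: population
#' medians 16.4 / 14.8 / 12.4 g/dl for the high-altitude, mid and low
#' populations living at 3202 / 1407 / 1097 m.  The per-population
#' baseline is tuned so that, at the default effects, simulated medians
#' approximate these values; they are calibration defaults of the
#' generator, not fitted quantities.
#'
#' @param median_by_pop named target hemoglobin medians (g/dl).
#' @param altitude_by_pop named altitudes (m).
#' @param beta_altitude altitude fixed effect (g/dl per m).
#' @param causal_snp SNP id with a direct effect, or `NULL`.
#' @param causal_snp_effect effect size (g/dl per derived allele).
#' @param polygenic_var polygenic variance sigma^2_g.
#' @param residual_var residual variance sigma^2_e.
#' @param age_range uniform age range (years).
#' @param beta_age age fixed effect (g/dl per year), default 0.
#' @return List of class `pheno_sim_spec`.
#' @export
pheno_sim_spec <- function(median_by_pop = c(A = 16.4, B = 14.8, C = 12.4),
                           altitude_by_pop = c(A = 3202, B = 1407, C = 1097),
                           beta_altitude = 5e-4,
                           causal_snp = NULL,
                           causal_snp_effect = 0,
                           polygenic_var = 1.0,
                           residual_var = 0.5,
                           age_range = c(18, 65),
                           beta_age = 0) {
  stopifnot(polygenic_var >= 0, residual_var >= 0, all(median_by_pop > 0))
  structure(list(median_by_pop = median_by_pop,
                 altitude_by_pop = altitude_by_pop,
                 beta_altitude = beta_altitude,
                 causal_snp = causal_snp,
                 causal_snp_effect = causal_snp_effect,
                 polygenic_var = polygenic_var,
                 residual_var = residual_var,
                 age_range = age_range, beta_age = beta_age),
            class = "pheno_sim_spec")
}

#' Simulate hemoglobin phenotypes with polygenic and SNP effects
#'
#' hemoglobin_i = base_pop(i) + beta_alt * altitude_i + beta_age * age_i
#' + beta_g * dosage_i(causal SNP) + u_i + e_i, with
#' u ~ MVN(0, sigma^2_g K) and e ~ N(0, sigma^2_e).  The population
#' baseline absorbs the altitude and expected genetic contributions so
#' that population medians land near the spec's targets.
#'
#' @param gm a `genotype_matrix` (populations must be named in the
#'   spec's `median_by_pop`).
#' @param K kinship matrix matching `gm`'s samples, or `NULL` for
#'   identity.
#' @param spec a [pheno_sim_spec()].
#' @param seed integer seed.
#' @return List with `phenotypes` (a `phenotype_table`) and `truth`
#'   (effects used).
#' @export
simulate_phenotypes <- function(gm, K = NULL, spec = pheno_sim_spec(),
                                seed = 1) {
  set.seed(seed)
  n <- nrow(gm$samples)
  pop <- gm$samples$population
  unknown <- setdiff(unique(pop), names(spec$median_by_pop))
  if (length(unknown) > 0)
    stop("no median target for population(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(K)) K <- diag(n)
  if (nrow(K) != n || ncol(K) != n) stop("K dimensions do not match gm")

  altitude <- spec$altitude_by_pop[pop]
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  g <- rep(0, n)
  if (!is.null(spec$causal_snp) && spec$causal_snp_effect != 0) {
    j <- match(spec$causal_snp, gm$snps$id)
    if (is.na(j)) stop("causal SNP not in gm: ", spec$causal_snp)
    d <- gm$dosage[, j]
    d[is.na(d)] <- round(mean(d, na.rm = TRUE))
    g <- spec$causal_snp_effect * d
  }
  u <- rep(0, n)
  if (spec$polygenic_var > 0) {
    ev <- eigen(K, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    u <- as.vector(ev$vectors %*% (sqrt(spec$polygenic_var * lam) *
                                     stats::rnorm(n)))
  }
  e <- stats::rnorm(n, 0, sqrt(spec$residual_var))

  base <- spec$median_by_pop[pop] - spec$beta_altitude * altitude -
    spec$beta_age * mean(spec$age_range)
  # centre the genetic contribution per population so medians stay on
  # target even with a common causal allele
  for (p in unique(pop)) {
    rows <- pop == p
    base[rows] <- base[rows] - stats::median(g[rows])
  }
  hb <- base + spec$beta_altitude * altitude + spec$beta_age * age +
    g + u + e
  pheno <- data.frame(sample = gm$samples$id,
                      hemoglobin_gdl = as.numeric(hb),
                      age = age,
                      altitude_m = as.numeric(altitude),
                      population = pop, stringsAsFactors = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")
  list(phenotypes = pheno,
       truth = list(causal_snp = spec$causal_snp,
                    causal_snp_effect = spec$causal_snp_effect,
                    beta_altitude = spec$beta_altitude,
                    polygenic = u, residual = e))
}

#' Simulate a monotone genetic map
#'
#' Anchors are evenly spaced over the region; each interval's rate is
#' the nominal rate times a mean-one log-normal jitter factor, so the
#' expected total map length equals rate x length.
#'
#' @param region_length_bp region length.
#' @param rate_cM_per_Mb nominal recombination rate.
#' @param jitter log-normal sd of the per-interval rate (0 = exactly
#'   linear).
#' @param seed integer seed.
#' @param n_intervals number of anchor intervals (default 100).
#' @param chrom chromosome label.
#' @return A `genetic_map`.
#' @export
simulate_genetic_map <- function(region_length_bp, rate_cM_per_Mb,
                                 jitter = 0, seed = 1,
                                 n_intervals = 100, chrom = "1") {
  stopifnot(region_length_bp > 0, rate_cM_per_Mb > 0)
  set.seed(seed)
  # anchors span [1, L+1] so the covered physical length is exactly L
  bp <- round(seq(1, region_length_bp + 1, length.out = n_intervals + 1))
  fac <- if (jitter > 0)
    exp(stats::rnorm(n_intervals, -jitter^2 / 2, jitter)) else
      rep(1, n_intervals)
  rate <- rate_cM_per_Mb * fac
  cm <- c(0, cumsum(rate * diff(bp) / 1e6))
  genetic_map(bp, cm, chrom = chrom)
}
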