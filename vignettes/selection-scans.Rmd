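---
title: "Selection scans and hemoglobin association with altsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and hemoglobin association with altsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altsel)
```

## What the package does

`altsel` is a desk-scale re-implementation of the analysis pipeline used to
look for recent, regionally restricted positive selection in a small
high-altitude population sample and to test the resulting candidate regions
for association with hemoglobin concentration.  The design centres on three
populations: a focal high-altitude population (A), a neighbouring
low-altitude population (B), and a more distant reference population (C),
with four complementary genome-wide statistics (F~ST~, LSBL, iHS, XP-CLR),
empirical top-0.1% outlier calling, gene-window pathway enrichment, a
core-haplotype frequency contrast, and an EMMAX-style mixed-model
association of hemoglobin with age and altitude as covariates.

Because the original genotypes are controlled-access, the package ships a
synthetic-data module that generates cohorts with the statistical structure
the analyses assume, together with truth tables, so every stage can be
tested as a recovery problem with known answers.

## Models and statistics

### Weir–Cockerham F~ST~

Per SNP, the two-population Weir–Cockerham (1984) estimator
$\hat\theta = a/(a+b+c)$ is computed from called sample sizes, allele
frequencies and observed heterozygosities via the among-population (a),
among-individual (b) and within-individual (c) variance components.  The
raw value is kept (it can be negative); SNPs monomorphic in both
populations, where $a+b+c = 0$, are flagged unestimable rather than given
a number, and are excluded from empirical distributions.

### Locus-specific branch length

With pairwise F~ST~ as branch distances on the three-population star tree,

$$\mathrm{LSBL}_A = \frac{d_{AB} + d_{AC} - d_{BC}}{2},$$

which isolates frequency change on the focal branch.  Negative pairwise
distances are clamped to zero *only inside LSBL* (tree distances cannot be
negative); the F~ST~ score tables keep the raw estimator so the empirical
F~ST~ distribution is unaffected.  The three branch lengths of a SNP always
sum to half its (clamped) distance sum, which the tests assert exactly.

### EHH and iHS

EHH at map offset $x$ from a core allele is the probability that two
random carrier haplotypes are identical at every SNP between the core and
$x$: $\sum_h \binom{n_h}{2} / \binom{n_c}{2}$ over identity classes $h$.
The walk extends SNP by SNP until EHH < 0.05, a physical gap > 200 kb, or
the end of the chromosome; the last two cases flag the side as truncated.
iHH is the trapezoid integral of the two-sided curve against cM, and the
unstandardized score is $\ln(iHH_A/iHH_D)$, so unusually long *derived*
haplotypes give negative scores.  SNPs with a truncated side are undefined
and never enter standardization.  Standardization subtracts the mean and
divides by the population SD within 20 equal-width derived-frequency bins
on [0.05, 0.95]; bins with fewer than 20 defined scores are merged into
their smaller neighbour.  After standardization every occupied bin has
mean 0 and variance 1 to ~1e-15, which the acceptance tests assert at
1e-10.

### XP-CLR-style composite likelihood

The scan slides windows of 0.005 cM, advanced by 5 kb, across the region.
Under the null, the objective population's allele count $k_j \sim
\mathrm{Binom}(n, p')$ where $p'$ follows a truncated normal around the
reference frequency $p_B$ with variance $\omega\, p_B(1-p_B)$ and point
masses at 0 and 1 (the mass of the normal outside [0,1]); $\omega$ is fit
genome-wide by matching the variance of $p_A - p_B$ (method of moments).
Under the sweep alternative, a lineage at map distance $r$ Morgans from
the window centre escapes with probability $c = 1 - q_0^{\,r/s}$, with
$q_0 = 1/(2N_e)$ and $N_e = 15{,}700$; an escaping lineage keeps its
drifted frequency while a hitchhiking one takes the swept haplotype's
allele (Bernoulli($p'$)), giving sampling frequency $c\,p' + (1-c)B$.
The score is $2(\max_s \ell_1(s) - \ell_0) \ge 0$, maximized over 30
log-spaced $s$ in [1e-5, 0.5] ($s \to 0$ recovers the null exactly, so
the score is floored at zero by construction).  SNPs in near-perfect LD
($r^2 > 0.95$ within a greedy group, measured in the reference
haplotypes) share weight $1/\text{group size}$.  Integrals use fixed
64-point Gauss–Legendre quadrature on [0,1].  This likelihood is the
package's own concrete instantiation of the cross-population CLR idea;
its guarantees are property-based (null score ~0, allele-label symmetry,
localization of simulated sweeps), not bit-compatibility with any
external executable.

### Mixed-model association

The null model $y = X\beta + u + e$, $\mathrm{Var}(y) = \sigma_g^2 K +
\sigma_e^2 I$ with the IBS kinship $K_{ij} = \overline{(2 - |g_i -
g_j|)/2}$, is fitted once by REML over $\delta = \sigma_e^2/\sigma_g^2$
using the spectral decomposition of $K$ (an 81-point log grid on
[1e-10, 1e10] brackets the mode; `optimize()` refines it).  Every SNP is
then tested by GLS in the rotated space with $\delta$ held fixed — the
defining EMMAX approximation — with the residual scale re-estimated per
marker, so with $K = I$ and no covariates the test is *exactly* ordinary
least squares.  SNPs with fewer than three genotype classes among the
tested samples are excluded before testing (a `min_genotype_classes = 2`
switch gives the literal "two genotypes" reading).  Benjamini–Hochberg
adjustment is applied to the tested SNPs.  If $K$ has a negative
eigenvalue, $(|\lambda_{\min}| + 10^{-8})I$ is added once and flagged.

The group-level hemoglobin contrast uses the Kruskal–Wallis rank test on
the three population samples; a two-group high/low comparison is the same
call with relabelled groups.

### Relatedness and structure

Pi-hat is the PLINK-style method-of-moments IBD estimate from observed
IBS state counts and their frequency-conditional expectations, clipped to
[0,1]; the finite-sample allele-frequency bias corrections of the
original implementation are omitted (at array scale they are negligible,
and the estimator is validated against duplicate and parent–offspring
expectations).  Exclusion is greedy: while any pair exceeds 0.25, the
member with more over-threshold partners is dropped (ties: higher mean
pi-hat, then input order).  PCA mean-imputes missing dosages per SNP,
centres but does not scale, and fixes each component's sign by its
largest-magnitude loading; LD pruning is PLINK-style greedy windowed
pruning (50 SNPs / step 5 / r² 0.5 — the window and step are the cited
tool's defaults, only the cutoff is stated by the study design).

## The synthetic cohorts

`simulate_bn_genotypes()` draws, per SNP, an ancestral frequency
$p \sim U(0.05, 0.95)$ and population frequencies from the
Balding–Nichols Beta$(p(1-F)/F,\ (1-p)(1-F)/F)$ with genotypes
Binomial(2, freq).  Default sample sizes (27/19/113) mirror the study
cohort; SNP spacing (~3 kb) matches a 1M array.  Planted outlier SNPs
force the population-A frequency to a target (default 0.9) while B and C
sit at the ancestral frequency; the outliers' ancestral frequency is
drawn from the lower half of its range so the plant is a genuine
focal-branch shift.

`simulate_sweep_haplotypes()` builds neutral haplotypes as mosaics of a
20-founder panel (switch probability 0.1 per SNP) and imposes an
incomplete sweep in population A: carriers up to the target frequency
(default 0.482) copy one template haplotype out to exponentially
distributed breakpoints on each side, with per-bp rate = recombination
rate (Morgans/bp) × `sweep_time_gen` (default 600 generations), giving a
mean shared flank of ~170 kb at 1 cM/Mb.  Population B receives its
carriers (default frequency 0.026) without haplotype replacement.  The
default region is 3 Mb — deliberately much longer than the swept
segment — so that iHS standardization is referenced against a
predominantly neutral background, as it would be in a genome-wide scan;
standardizing inside a region that is mostly sweep would inflate the bin
SDs and is not a situation the statistic is defined for.

`simulate_outgroup_alleles()` gives all three outgroups the truth
ancestral allele at 95% of SNPs and plants, at the rest, an outgroup
conflict, a non-segregating base, or total missingness — the three ways
polarization must discard a SNP.  `simulate_phenotypes()` generates
hemoglobin as population baseline + altitude and age effects + optional
causal-SNP effect + polygenic term $u \sim N(0, \sigma_g^2 K)$ +
residual; baselines are tuned so medians land near 16.4/14.8/12.4 g/dl
at the default effects.  The variance split (1.0/0.5) reflects a
strongly heritable trait.

What the generators do **not** emulate: coalescent genealogies and
realistic LD decay, mutation-rate heterogeneity, ascertainment bias of
array content, X chromosomes, and demographic events beyond a star
phylogeny.  Passing recovery tests therefore demonstrates that the
statistics detect the signals they are defined on — not that the pipeline
is calibrated for any particular real demography.

## Numerical choices and degenerate inputs

* Nearest-rank empirical quantile with a strict-greater outlier rule
  (ties at the threshold are not outliers), matching the
  "statistic > threshold" convention.
* Genotype QC: the SNP completeness rule is inclusive (≥ 0.95), the
  sample call-rate rule strict (> 0.95), following the two phrasings of
  array QC; SNPs are filtered before samples and the filter is
  idempotent.
* Reference frequencies in the XP-CLR drift density are clamped away
  from 0/1 by half a chromosome count (1/(4N~e~)) to avoid a degenerate
  density.
* Monomorphic SNPs and pairs with undefined LD return `NA`/flags, never
  silently 0.
* All generators are bit-reproducible from (spec, seed); the pipeline
  derives per-stage seeds from the global seed by a fixed affine hash so
  stages can be re-run alone.

## Problem sizes used by the test-suite

The recovery tests run at sizes chosen to finish on a single CPU while
keeping the estimators in their working range: 20,000 SNPs for the drift
recovery (F = 0.05, 30+30 samples), 25 seeds of the default 3 Mb /
900-SNP / 200-haplotype sweep for iHS, 20 seeds for XP-CLR localization,
and 50 seeds of n = 200 for variance-component recovery.  The bundled
demo pipeline uses 1,500 array SNPs and a 200-SNP sweep region and runs
in well under a minute.

## Known limitations

* The XP-CLR likelihood is a self-contained instantiation, not a
  re-implementation of the original software; scores are comparable
  within a run, not across tools.
* iHS near chromosome edges or large gaps is undefined by construction;
  regions shorter than a few sweep lengths leave little neutral
  reference for standardization.
* The moment-based pi-hat loses accuracy for small SNP counts (pairs
  with < 50 informative SNPs are flagged) and assumes cohort allele
  frequencies are a fair reference.
* The EMMAX approximation holds the variance ratio fixed across SNPs;
  for strongly associated SNPs an exact per-SNP REML would differ
  slightly.
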