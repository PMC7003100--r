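---
title: "Quantitative genetic dissection of NAM populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetic dissection of NAM populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`namqg` implements the analysis chain used to dissect low-heritability
quantitative traits (yield components and the like) in nested association
mapping (NAM) panels: many biparental recombinant-inbred-line (RIL)
families that share one common parent. This vignette is the package's own
account of the models, their assumptions, the tunable parameters, and the
numerical choices made where the design was genuinely open. The worked
example in the README shows the code in action; nothing stated here goes
beyond what the package's tests and acceptance script themselves compute.

## The synthetic NAM generator

Every statistical claim in the test suite is made against data from
`simulate_nam()`, whose defaults emulate a soybean-style NAM study:
40 families of ~140 RILs sharing a common parent, ~4240 biallelic SNPs on
20 chromosomes, six environments over three years in a 7:1 line-to-check
augmented design, and a trait with low plot-level heritability.

* **Founders** are fully inbred (codes 0/2). The counted allele is the
  alternate-founder allele; its frequency among alternate founders is
  drawn per locus from `founder_maf_range`. Founder genotypes are drawn
  independently across loci, so there is no founder-level linkage
  disequilibrium — RIL LD arises purely from co-segregation.
* **Meiosis** uses the Haldane (no-interference) map function,
  r = (1 − e^(−2d/100))/2 for d in cM, the simplest defensible model;
  line derivation is single-seed descent for `selfing_generations`
  (default 5) rounds with residual heterozygotes coded 1. No selection
  acts during derivation.
* **Genetic values** are sums of additive QTL effects and
  additive-by-additive pairwise products on centered codes — exactly the
  effect types the downstream G2A model represents. Effects are rescaled
  so the realized additive and epistatic variances hit their target
  fractions of a unit total plot variance; the residual variance is the
  remainder after also budgeting `gxe_sd^2` (independent
  family-by-environment normal deviations) and `spatial_gradient_sd^2`
  (a linear trend plus one low-frequency sinusoid per block, giving the
  moving-average covariate something detectable without committing to an
  AR error structure).
* **Checks** are three fixed founder genotypes interleaved every
  `check_ratio` plots; they exist for the spatial correction and are
  excluded from all genetic reporting.

What the generator does **not** emulate: realistic LD decay and founder
relatedness, dominance, selection, genotyping error, family-to-family
heterogeneity of genetic architecture, and non-Gaussian trait error. A
passing test therefore certifies the estimators under the model's own
assumptions, not their robustness on real germplasm.

## Stage 1: genetic merit

Per trait, `fit_merit()` fits

y = mu + beta·f(s) + Z u + W g + e,

where f(s) is the moving-average of neighboring plots within the
(environment, block) — window `c(1, 1)` by default, i.e. rook plus
diagonal neighbors, computed from raw trait values and entered as a fixed
regression — u is the random genotype effect, g the random block effect,
and the per-environment inverse phenotypic variances act as residual
precision weights. Variance components come from EM-REML on Henderson's
mixed-model equations (relative log-likelihood tolerance 1e-8, at most
500 iterations). EM was chosen over Newton-type REML for its monotone,
floor-respecting updates; its estimates are checked in the tests against
an exhaustive grid search of the directly-evaluated restricted
likelihood.

Broad-sense heritability on an entry-mean basis is
H = s2u / (s2u + s2e / r), with r the mean plot count per non-check
entry across all environments. Each genotype's reliability is
H_j = 1 − PEV_j / s2u (the standard definition; PEV from the MME
inverse), and the deregressed value y_j = u_j / H_j removes the
heterogeneous shrinkage before any genomic modeling. When s2u collapses
(≤ 1e-9), H is reported as 0, deregression is undefined and flagged.
Non-convergence warns and carries the log-likelihood trace rather than
erroring, because the block component routinely crawls toward zero on
small trials while the genotype solutions are stable.

## Kernels and narrow-sense heritability

With M the marker matrix centered at twice the counted-allele frequency,
G = MM′ is trace-normalized to the additive kernel K = G·n/tr(G), and
the additive-by-additive kernel is the Hadamard square
Q = (G⊙G)·n/tr(G⊙G). The square is taken on the unnormalized G and
renormalized by its own trace; squaring the normalized K instead differs
only by a scalar that the normalizer absorbs.

`snp_blup_h2()` fits the ridge model y = mu + Ma + eps by REML on the
eigenbasis of MM′ and reports h2 = s2a·S / (s2a·S + s2eps). The additive
scale S deserves a note: the textbook choice S = 2Σp(1−p) is the
marker-variance sum of a Hardy–Weinberg population, but a RIL panel is
(nearly) fully inbred, where a biallelic marker contributes
(1+F)·2pq ≈ 4pq of dosage variance. Using the HW sum on inbred data
understates the genomic variance by about half, so the default scale is
the empirical marker-variance sum Σ_j var(m_j) — identical to 2Σpq under
HW and self-consistent on any panel; `scale = "hw"` retains the literal
expression. The QTL-subset scenario re-estimates s2a on the subset
rather than reusing the all-marker estimate.

## G2A variance decomposition and genetic correlations

`fit_g2a()` fits y = mu + psi + omega + eps with psi ~ N(0, K s2psi),
omega ~ N(0, Q s2omega) by EM-REML on the phenotypic covariance
(component floor 1e-10, at most 2000 iterations). Within-family
decompositions rebuild K and Q from the family's own markers and allele
frequencies, because pooled kernels would leak across-family structure
into components that are meant to be within-family. Families below 10
individuals are skipped with a warning.

`fit_bivariate()` fits the two-trait GBLUP y_t = mu_t + psi_t + eps_t
with psi ~ N(0, K ⊗ Sigma_psi) and diagonal residual covariance. On the
eigenbasis of K the covariance is block-diagonal in 2×2 blocks, so each
EM sweep is O(n); the E-step uses the REML projection (fixed effects
integrated out). The additive genetic correlation is
rho_psi = sigma_12 / sqrt(sigma_11 sigma_22); the Pearson correlation of
the two BLUP vectors is reported alongside as the "genetic correlation".
Numerical guards: residual variances floored at 1e-8 of the trait
variance, the implied correlation clipped into [−1, 1], and fits whose
additive variances collapse are flagged degenerate. The same machinery
serves pleiotropy (two traits) and stability (one trait in two years);
year pairs default to all pairs.

The efficiency of indirect selection is exposed under two conventions,
E = rho·h2_i/h2_j (`"literal"`, the default) and E = rho·h_i/h_j
(`"falconer"`), because the source expression is typographically
ambiguous about whether the heritabilities enter squared; both are
monotone in rho, and E > 1 in either convention means indirect selection
beats direct.

## The tri-method genome scan

* **MLM** (`scan_mlm`): the null polygenic model y = mu + psi + e is
  fitted once by REML on the eigenbasis of K; each marker then adds
  family-nested codes X (one column per family in which the marker
  segregates — non-segregating columns would make the design singular)
  with a common random-effect variance s2beta profiled by REML while the
  polygenic and residual components stay at their null estimates. This
  keeps the eigendecomposition shared across markers; the cost is the
  usual two-stage approximation. The LRT is referred to chi-square with
  1 df (a boundary-anticonservative choice made deliberately for
  simplicity; `mixture = TRUE` applies the 50:50 chi-square mixture).
  The genome-wide line is the two-sided Bonferroni threshold
  −log10(0.025/m), which is 5.23 at m = 4240.
* **BayesCpi** (`scan_bayescpi`): a Gibbs sampler in which each marker
  carries an inclusion indicator, the exclusion probability pi is
  resampled from Beta(counts + 1), and the common slab variance follows
  a scaled-inverse-chi-square with nu0 = 5 and scale
  S_beta = 0.5·var(y)/(MSx·(1 − pi)) recomputed each iteration — the
  prior-heritability-0.5 calibration, with MSx the marker-variance sum.
  Default chain 20000 iterations, 2000 burn-in, no thinning. The
  statistic is −log10(1 − model frequency) with the two-sided line
  −log10(0.025) = 1.6; model frequencies are capped just below 1 so the
  statistic stays finite. Because all markers are fitted jointly, no
  multiplicity adjustment applies.
* **RFR** (`scan_rfr`): a `ranger` regression forest (defaults 10000
  trees, mtry = 65 ≈ sqrt(4240)) ranked by impurity importance. The
  significance line is the global empirical threshold: the (1 − alpha)
  quantile of the maximum importance over phenotype permutations
  (default 1000), which makes no distributional assumption.

`qtl_effects()` reports least-squares allele-substitution effects of
selected markers on each trait after removing family means from both
sides; with the counted allele anchored to the alternate founders, a
negative effect means the desirable allele came from a founder parent.
`consensus_table()` is exact bookkeeping: the per-marker union of the
per-method significance flags.

## Genomic prediction and cross-validation geometry

`fit_gblup()` is ridge-REML on the kernel (lambda = s2e/s2u from the
training subset; held-out individuals predicted through their kernel
rows). `fit_bayesb()` fixes the null-effect probability at pi = 0.95 and
gives each marker its own slab variance, scaled-inverse-chi-square with
nu0 = 10 and S_beta = 0.5·var(y)/MSx; the CV default chain is 5000
iterations with 500 burn-in — a speed/accuracy knob that posterior-mean
predictions are insensitive to at these sizes.

`cross_validate()` implements three geometries. Across-family: 5-fold
partitions of the whole panel, PA (Pearson correlation of predicted vs
observed deregressed values) pooled per fold, 25 repetitions by default.
Within-family: each family is cross-validated on its own — folds inside
the family, the model calibrated only on the family's remaining lines,
PA within the family. Calibrating instead on all families minus the fold
would leak full-sibling information and invert the scheme's meaning; the
small per-family calibration set is precisely what this scheme measures.
Leave-family-out: each family predicted from all the others. PA is never
pooled across families for the family-wise schemes, since family means
would inflate it (a Simpson's-paradox artifact). The kernel is built
once on the full panel and subset per fold.

## Problem sizes used by the tests

The test suite runs everything at desk scale, chosen once: parameter
recovery uses n = 2000 RILs (20 x 100) for SNP-BLUP h2 = 0.30, n = 1000
(10 x 100) for G2A truth (0.25, 0.25), and n = 800 (8 x 100) for the
bivariate correlation 0.4, each averaged over 10 seeds; scan power uses
a single 10%-variance QTL at n = 1500, m = 500; the null-size checks use
reduced chains (5000/500) and reduced forests (500 trees, 100
permutations, 20 null scans — under a true 5% rate, more than 3
significant scans out of 20 has probability below 2%, which is the
binomial bar the suite applies). The prediction-structure check keeps
the study's panel size (~1000 lines, 500 markers, 5-fold x 5-rep CV)
but arranges it as 25 families x 40 RILs: the leave-family-out scheme
draws its information from the many half-sib families sharing the
common parent, so collapsing the panel to very few large families
removes exactly the structure the comparison is about, while many
small families preserve it.

## Known limitations

Stage 1 is single-trait with a single moving-average covariate — no
AR1×AR1 or factor-analytic environment models. The G2A decomposition
stops at additive-by-additive pairs; dominance and higher-order
epistasis are out of scope. The MLM profiles only the marker variance
per marker (no per-marker re-estimation of the polygenic background),
and its chi-square reference is anticonservative at the boundary. The
bivariate model fixes the residual covariance diagonal. Imputation is
the within-family mode — adequate for RIL panels with low missingness,
not a substitute for haplotype-aware methods at high missingness.
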