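---
title: "Models and methods: cognitive and non-cognitive genetics of academic development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative
model behind the synthetic cohort, each estimator with its assumptions
and numerical choices, and what the test suite does and does not
establish about real data.

## 1. The scientific setting

Non-cognitive skills — academic motivation, attitudes to learning,
self-regulation — predict school achievement beyond cognitive ability,
and both twin and DNA-based designs suggest that the *genetic* link
between non-cognitive dispositions and achievement strengthens from
early childhood to the end of compulsory schooling. Testing this
developmental claim takes four coordinated designs:

1. phenotypic regressions of achievement on non-cognitive factors
   controlling for general cognitive ability (`g`) at each age;
2. twin variance decompositions that split the heritability of
   achievement into a part shared with `g`, a part shared with
   non-cognitive skills beyond `g`, and a residual;
3. polygenic scores for latent cognitive and non-cognitive genetic
   factors, obtained by a GWAS-by-subtraction structural model of GWAS
   summary statistics, whose prediction of achievement is tracked over
   age;
4. family-based designs — the within/between-family decomposition on DZ
   twins and PGS × SES interaction models — that probe whether those
   associations reflect direct genetic effects or familial confounding
   (indirect parental effects, stratification).

The package implements all four on a synthetic cohort with known truth.

## 2. The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions
under which every estimator is validated.

**LD panel.** SNP correlations are block-diagonal; within a block the
correlation decays as `r^|i-j|` (positive definite by construction).
`block_size` and `decay` accept patterns, so a panel can interleave
independent SNPs with high-LD blocks. The default panel (20,000 SNPs,
pattern 1,1,1,1,8 with decay 0.85 in the size-8 blocks) mixes LD scores
between 1 and ~4.5. That spread matters: LD-score regression separates
its slope from its intercept only through variation in the LD score, and
a panel with near-constant scores leaves the intercept unidentified.
MAFs are uniform on [0.05, 0.5]; allele pairs are drawn from the four
unambiguous combinations so strand-ambiguity filtering never silently
removes simulated SNPs.

**Families.** Parent genotypes are drawn haplotype-wise by thresholding
correlated Gaussians at the MAF quantile (Hardy–Weinberg with block LD);
offspring receive one parental haplotype per block (crossover-free
segments), so MZ pairs are genotype-identical, DZ pairs are related 0.5
in expectation, and within-block LD is preserved in offspring. An
optional stratification axis (one value per family) shifts every SNP's
liability threshold, creating a geography-like allele-frequency gradient.

**Phenotypes.** Three latent genetic factors are weighted sums over
disjoint causal SNP sets (a config flag instead overlaps the cognitive
and non-cognitive sets with effect correlation 0.15, echoing the modest
cognitive/non-cognitive genetic overlap): `g_cog`, `g_noncog`, and an
achievement-specific `g_spec`. Latent traits (`cog`, `ncs_edu`,
`ncs_selfreg`) follow ACE structure per age: `sqrt(a2) g + sqrt(c2) C +
sqrt(e2) E`, with C and E redrawn each age so cross-age stability flows
through genetics only — a deliberate simplification. Achievement at age
`t` is

```
delta_cog(t) g_cog + delta_noncog(t) g_noncog + delta_spec(t) g_spec
  + eta_cog gpar_cog + eta_noncog gpar_noncog
  + ses_effect SES + strat_strength u + sqrt(c2) C + sqrt(e2_t) E
```

where `gpar` is the parental mean genetic value — the indirect
(passive gene–environment correlation / demographic) pathway. The
non-shared remainder `e2_t` is solved analytically so the generating
variance is exactly 1 (using `var(delta g + eta gpar) = delta^2 +
eta^2/2 + delta eta`, since `cov(g_child, gpar) = 1/2`); configured
deltas are therefore standardized effect sizes, and the generator errors
— naming the age — if the shares overcommit the budget. SES is exogenous
(independent of genotype) unless the stratification axis is enabled;
this keeps the benchmark identity "no indirect effects and no
stratification implies equal within- and between-family coefficients"
exact in the generating model.

**Defaults as study conditions.** Ages 7/9/12/16. `delta_cog` flat at
0.17 with `eta_cog = 0.12`, and `delta_noncog = (0.06, 0.08, 0.11,
0.15)` with `eta_noncog = 0.10`: these reproduce, at population level, a
flat cognitive PGS effect near 0.25 and a non-cognitive effect rising
from ~0.10 to ~0.22, with within-family effects roughly half the
population ones — the qualitative result surface the analysis targets.
Latent ACE shares are 0.5/0.2/0.3 (cognitive) and 0.4/0.2/0.4
(non-cognitive), consistent with moderate (~30–50%) non-cognitive
heritability; `delta_spec = 0.55` leaves a substantial
achievement-specific genetic share. Indicator loadings default to 0.7;
raters (self/parent/teacher) see the latent through a reliability-0.7
lens with rater-specific disturbances — the generator's answer to the
open question of how rater disagreement arises, parameterized rather
than asserted.

**GWAS summary statistics.** Eight traits (CP, SD, ME, TM, RT, EA, IN,
DE) are generated either from an explicit genetic covariance target
(`simulate_sumstats`: per-SNP joint effects with covariance `S/M`,
marginals `beta_hat = D beta + noise(D/N)` blockwise, so `E[chi2] = 1 +
N h2 l_j / M`) or, in the pipeline, from the cohort's own causal vectors
through a loading matrix (`simulate_sumstats_factor`), keeping the GWAS
traits genetically consistent with the cohort. The default loadings
(Cog: 0.9/0.5/0.5/0.4/0.3 on the cognitive tasks, 0.4/0.3/−0.3 on
EA/IN/DE; NonCog: 0.6/0.45/−0.5 on EA/IN/DE; deprivation negative) give
trait heritabilities in a plausible 0.1–0.9 range at GWAS N = 100,000
per trait — deliberately "desk-scale" relative to real consortium GWAS.

**Ancestry covariates.** The 10 "principal components" supplied as
covariates are a labelled synthetic stand-in: PC1 is the stratification
axis plus noise, PCs 2–10 pure noise. They play the covariate role
without an eigen-decomposition of the genotype matrix.

## 3. Estimators

**One-factor CFA.** ML on the Pearson correlation matrix of complete
cases, identified by unit factor variance and a positive first loading;
residual variances bounded at zero (Heywood cases flagged). A fitted
factor that explains no covariance (all implied cross-covariances below
0.05) is flagged degenerate — this also covers the single-indicator
ridge, where one loading is unidentified because the model can park the
factor on one variable without touching the likelihood. Factor scores
are regression-method (`lambda' Sigma^-1 x`), which shrink (SD ≤ 1);
missing-data handling is complete-case per analysis, with the `g`
composite tolerating one missing test (flagged).

**Twin models.** All ML fits work on zygosity-group moment matrices
under the classical assumptions (additive genetic cross-twin correlation
1 for MZ / 0.5 for DZ, shared environment 1, non-shared 0, equal
environments across zygosities). Variance components are parameterized
by their square roots, so non-negativity is automatic and boundary
solutions (e.g. rMZ < rDZ pinning `a` at 0) are flagged rather than
failed. Standardization is on the pooled MZ+DZ sample; double entry is
used for descriptive correlations only, never inside ML fits. CIs are
nonparametric bootstrap over families (resampling within zygosity),
defaulting to B = 500 in the API and B = 100 in the pipeline. The
trivariate Cholesky enters traits in the order g → NCS → achievement —
the research question fixes this order, and the third row of squared
standardized A-paths is the headline decomposition. Optimizer: BFGS with
moment-based starts (A from `2(X_MZ − X_DZ)` projected to PSD, etc.) and
`reltol 1e-14`; on exact model-implied moments the fits reproduce
generating parameters to ~1e-6, which the tests use as a deterministic
oracle. The common pathway model fixes the latent variance to 1 via a
unit-sphere parameterization of its A/C/E paths.

**LD-score regression.** Chi-squares regress on `N l_j / M` with a free
intercept and two-step weights (first pass `1/max(l,1)`, second pass
divided by the squared first-pass fitted mean). SEs come from a
delete-one-block jackknife over 200 contiguous SNP blocks, computed from
block-partitioned cross-products so the joint jackknife of all 36
elements of an 8-trait genetic covariance matrix is a single pass. For
LD-free panels the intercept is collinear with the slope;
`free_intercept = FALSE` pins it at 1 (the no-confounding value), and
the estimator refuses the unidentified case rather than returning noise.
Cross-trait weights use the product of the per-trait fitted second
moments plus the squared fitted co-moment; because all three step-one
fits share weights, a trait's genetic correlation with itself is exactly
1 — a fixed point the tests assert.

**GWAS-by-subtraction.** The genetic covariance matrix is fitted by
diagonally weighted least squares — `(s − sigma(theta))' diag(V)^{-1}
(s − sigma(theta))` over the half-vectorized unique elements — with
sandwich SEs using the full jackknife `V`. Residual variances enter as
squared free parameters, so plain BFGS applies (a bound-constrained
variant occasionally aborted inside its line search on noisy inputs);
Heywood residuals land at 0 and are flagged. Factor scale is fixed by
unit factor variances; signs anchor on positive CP (Cog) and EA (NonCog)
loadings. Per-SNP effects: with loadings fixed, each SNP's standardized
indicator effects `Z_i/sqrt(N_i)` regress on the two loading columns
with weights `N_i`; since the design is shared genome-wide this is one
2×K solve, applied as a matrix product, with SEs propagated through the
same linear map. The two-indicator reduction (CP and EA only) has the
closed form `beta_Cog = beta_CP / lambda_Cog,CP`, `beta_NonCog =
(beta_EA − lambda_Cog,EA beta_Cog) / lambda_NonCog,EA`, which the solver
reproduces to machine precision. Latent sumstats carry per-SNP SEs; an
effective `N = 1/SE^2` is attached so they can flow into LDSC and
LDpred like measured traits.

**LDpred-inf.** The infinitesimal posterior mean solves `(M/(N h2) I +
D) beta_inf = beta_marginal` per LD block against the simulation's own
panel (the analogue of using the target sample as LD reference). The
shrinkage heritability defaults to the LDSC estimate of the input — as
in real usage, where the truth is unknown — with an override for
controlled experiments. Identity LD reduces to scalar shrinkage
`N h2/(N h2 + M)`, and the block solver matches a dense whole-genome
solve to 1e-8; both are frozen oracles in the tests. Weights are emitted
per-allele; scoring aligns effect alleles against the genotype coding,
treats a flip as a sign change (the constant offset a flip would add is
irrelevant after standardization), and drops unresolvable SNPs with a
count.

**Association layer.** Population-level fits are OLS on standardized
variables with cluster (family) sandwich SEs and no small-sample
multiplier — the estimating-equation solution under an independence
working correlation; with singleton clusters this is exactly HC0. The
within/between decomposition regresses achievement on the family-mean
PGS and each twin's deviation from it, in a mixed model with family
random intercept fitted by ML (REML is available but ML keeps nested
models comparable); MZ pairs are refused since they carry no within-pair
genetic variance. The GxE model adds PGS × SES interactions and — since
the enumeration of "two-way interactions between predictors and
covariates" is genuinely open — optionally each predictor × covariate
interaction, controlled by a flag. SES strata use rank-based quartile
cutpoints (exact 25/50/25 splits when n divides by 4) with slopes
standardized on the full sample. BH adjustment wraps `stats::p.adjust`
behind input validation. The developmental profile refits the
population model per age and summarizes the trend as the OLS slope of
beta over age with a family-bootstrap CI.

## 4. Validation design and problem sizes

Every estimator has a deterministic oracle (exact-moment or closed-form
or dense-solver equivalence) plus stochastic parameter-recovery checks
at sizes chosen so the Monte-Carlo error is well inside the asserted
band: ACE at 5,000+5,000 pairs (±0.03 on shares), the Cholesky split at
10,000 pairs per zygosity (±0.04 on squared paths; at half that size the
sampling SD of a squared cross-path is ~0.034, so the band would be a
coin flip), LDSC at M = 20,000 / N = 50,000 on the mixed panel (h2 SD
~0.012), within/between at 10,000 DZ pairs (±0.02 on the direct
effect), and the developmental trajectory at 10,000+10,000 pairs so the
smallest schedule step (0.02) is ~2 SE. Family-based criteria use the
truth-table genetic values as scores: the recovery identities are exact
only for noiseless scores, while the pipeline demonstrates the same
logic with estimated LDpred scores. Subtraction-model inference is
validated by calibration: across replicate simulations the per-loading
`(estimate − truth)/SE` draws must show their nominal 2-SE exceedance
rate and vanishing mean — a sharper requirement than any single joint
draw, whose pass probability for 11 loadings is only ~60% even for a
perfect estimator. Coverage studies (bootstrap CIs, Fisher-z, GxE nulls)
run at reduced replicate counts with bands widened to the corresponding
binomial error.

What passing does *not* show: the generator draws Gaussian effects,
unlinked blocks, random mating, exogenous SES, no selection,
missingness-free phenotypes, and rater noise that is conditionally
independent given the latent. Real cohorts violate all of these;
estimates on real data inherit those caveats (notably, adjusting for a
heritable covariate such as SES can itself bias multivariable PGS
models).

## 5. Reproducibility

All randomness derives from one master seed through named substreams
(`substream_seed(master, "genotypes")` etc.), so adding a stage never
perturbs another stage's draws and any intermediate can be regenerated
in isolation. The pipeline writes a manifest with the md5 of every
output table keyed by a hash of the canonical YAML configuration
(excluding the output path); identical configuration and seed reproduce
identical checksums, which the tests assert at both toy and default
scale. The default pipeline (2,000 + 2,000 pairs, 20,000 SNPs) runs in
a few minutes on one CPU; the heavier validation conditions above are
exercised in the acceptance tests and `scripts/acceptance.R`.

## 6. Known limitations

* No assortative mating, X chromosome, imputation error, or genotype QC
  artefacts in the generator (declared non-goals).
* The common pathway and Cholesky fits assume complete pairs;
  single-member families are dropped, not modelled.
* LDSC uses fixed contiguous jackknife blocks (200), not
  recombination-aware windows.
* The per-SNP subtraction solve conditions on point-estimated loadings;
  loading uncertainty is not propagated into per-SNP SEs (it is second
  order at GWAS sample sizes, but real pipelines share the limitation).
* Latent sumstats carry `N_eff = 1/SE^2` rather than a model-based
  effective sample size.
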