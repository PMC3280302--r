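---
title: "Longitudinal SNP association and joint-effect burden modelling of BMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal SNP association and joint-effect burden modelling of BMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longbmi)
```

## The analysis problem

Candidate-SNP replication studies of body mass index usually test one BMI
measurement per subject. A longitudinal growth cohort instead observes each
subject's BMI repeatedly across childhood (ages 3 to just under 18) and
adulthood (18 to 45), which multiplies the number of observations several
fold and lets genetic effects be examined across the whole course of
obesity development. `longbmi` implements the full analysis toolchain for
this design:

* per-SNP quality control (minor allele frequency, heterozygosity,
  Hardy-Weinberg equilibrium);
* single-SNP scans of longitudinal BMI per age stratum with a linear mixed
  model, under both an additive and a general genetic coding, combined by a
  minimum-q-value FDR rule;
* a cross-sectional scan of SNP effects on birth weight;
* SNP-by-age and SNP-by-birth-weight interaction tests;
* a heuristic forward search for the best joint-effect allele burden model
  under a modified AIC, with a permutation empirical p-value;
* analytic power calculations for variance-explained effect sizes;
* a synthetic cohort generator that emulates the design, so that every
  stage is testable without access to individual-level study data (which
  are not publicly deposited for cohorts of this kind).

## The longitudinal mixed model

All longitudinal tests are built on the Gaussian linear mixed model

$$ BMI_{ij} = \beta_0 + \beta_a \, age_{ij} + \beta_s \, sex_i +
\beta_b \, bw_i + g(\text{SNP}_i)^\top\gamma + b_{0i} + b_{1i} \, age_{ij}
+ \varepsilon_{ij}, $$

where $(b_{0i}, b_{1i})$ is a per-subject random intercept and age slope
with an unstructured $2 \times 2$ covariance and $\varepsilon_{ij}$ is
i.i.d. residual noise. The genetic term $g(\cdot)$ is a minor-allele dosage
(additive coding, 1 df), a pair of genotype-class indicators against the
major-allele homozygote (general coding, 2 df), or an allele burden score
(joint search). Interaction models add genotype-by-age or
genotype-by-birth-weight products while retaining all main effects.

Two deliberate modelling choices:

* **Maximum likelihood, never REML.** The forward search compares models
  that differ in their fixed effects, and the modified AIC is defined
  through the maximized likelihood; REML likelihoods are not comparable
  across fixed-effect structures.
* **"A random effect of age" is intercept + slope.** A slope-only random
  term leaves between-subject level differences unmodelled in growth data,
  so the default random structure is the correlated intercept + slope; a
  slope-only structure remains available via `random = "slope"` in
  `fit_lmm()` for sensitivity analyses.

Age enters uncentred (raw years), so interaction coefficients read directly
as "effect change per one-year increase in age", and birth-weight
interactions as "per one-kilogram increase in birth weight".

### Estimation

`fit_lmm()` maximizes the profiled ML deviance: the fixed effects and the
residual variance are profiled out in closed form, leaving a 3-parameter
search over the Cholesky factor of the relative random-effect covariance,
solved by Nelder-Mead with a fixed deterministic start (warm starts are
used internally when thousands of closely related models are refitted).
The per-subject cross-products are precomputed, so one deviance evaluation
costs $O(\text{subjects})$ small-matrix work; the hot loop is compiled
(RcppArmadillo). This engine is what makes the permutation null of the
joint search (tens of thousands of model refits) computable on one CPU.
The test suite verifies the engine against two independent routes: lme4's
`lmer(..., REML = FALSE)` on simulated fixtures (log-likelihood equal to
about 1e-5) and a brute-force multivariate-normal density evaluation on a
tiny instance (equal to 1e-6).

Numerical edge cases: a rank-deficient design is rejected with the
collinear columns named; noise-free data are handled by flooring the
profiled residual variance at a scale-relative epsilon (the fixed effects
remain exact); fits that do not converge are treated as missing by the
scans and as unavailable candidates by the search.

## Dual-coding scans and the minimum-q rule

Every SNP is tested under both codings because neither dominates: a
codominant inheritance pattern can make the general 2-df test much
stronger than the additive 1-df test, and vice versa. q-values are
computed per (stratum x coding) family — childhood and adulthood are
separate analyses, and pooling codings before adjustment would mix test
statistics with different degrees of freedom — and the per-variant q-value
is the smaller of the two codings' q-values. The family layout is a
documented choice (`fdr` engine and family composition are arguments), as
the alternative of pooling all 46 tests per stratum is also defensible;
results at the q = 0.05 threshold rarely differ in either direction.

Benjamini-Hochberg is the default q-value engine because it is
deterministic and assumption-light at 23-46 tests; Storey's
$\hat\pi_0$-adjusted estimator is provided (`storey_qvalues()`) but a
family of a few dozen tests is small for stable $\hat\pi_0$ estimation,
which is why it is not the default.

For reporting, general-model genotype effects are re-expressed against the
homozygote with the lower adjusted mean (`genotype_effects_report()`);
model fitting itself always keeps the major-allele homozygote baseline so
the design is stable.

## The forward joint-effect search

The burden score of a selected set $S$ of (SNP, reference allele) pairs is
the per-subject count of reference-allele copies summed over $S$ —
unweighted, one coefficient regardless of $|S|$. The search starts from the
covariates-only model and at each step evaluates every remaining (SNP x
allele) candidate by refitting the mixed model with the trial burden and
scoring it with the modified AIC

$$ \mathrm{mAIC} = 2\,(n_{\text{SNP}} + n_{\text{non-SNP}}) - 2 \ln L, $$

which penalizes per SNP added rather than per estimated coefficient (the
burden has one coefficient however many SNPs it sums — that is what makes
the criterion "modified"). $n_{\text{non-SNP}}$ counts the four non-genetic
fixed effects plus the four variance/covariance parameters; this count is
constant across all compared models, so selection is unaffected by the
convention, but it is documented and tested as stated. The minimum-AIC
candidate is accepted if it is strictly smaller than the current AIC (any
positive decrease continues the search; there is no minimum-decrease
threshold), selected SNPs are frozen (no backward elimination or allele
re-choice), and the search stops when no candidate improves.

Two structural facts shape the implementation:

* **Allele-flip degeneracy.** At the first step the two codings of a SNP
  ($d$ and $2-d$) span the same model space once an intercept is present,
  so their likelihoods tie exactly. Ties within 1e-8 are broken by
  preferring the allele whose burden coefficient is positive (so reported
  reference alleles follow the risk-allele convention), then the lower
  panel index; this makes the output deterministic and reportable.
  Mirroring the reference allele of *every* selected SNP simultaneously
  also leaves the likelihood unchanged (the intercept absorbs the shift),
  and the tests verify the minimized AIC is identical under that mirror.
* **Candidate evaluation is a full refit.** A score approximation would be
  faster, but the full refit is exact and the compiled engine keeps it
  affordable.

Missing dosages are mean-imputed per SNP inside the burden only (so the
score is defined for every subject); the single-SNP scans drop missing
genotypes pairwise instead.

The per-step variance trace reports the cumulative share of observed BMI
variance carried by the fitted burden predictor,
$100 \cdot \mathrm{Var}(\hat\beta\,S)/\mathrm{Var}(BMI)$ over
observations, and each selected SNP's single-variant share. This
definition is one of several possible "explained variance" readings; it is
adopted because it reproduces the qualitative behaviour expected of the
trace — the first selected SNP can carry a vanishingly small share (the
criterion optimizes the joint model, not the single-SNP effect) while the
cumulative share grows along the path. `plot()` on a search object draws
the cumulative (solid) and single-variant (dashed) traces with the
reference allele above each column.

### Permutation empirical p-value

The null distribution of the minimized AIC is generated by severing the
genotype-phenotype link and rerunning the *entire* search — including
allele selection — per permutation; the empirical p-value is the fraction
of permutations whose minimized AIC is at or below the observed one. The
default scheme permutes whole subject genotype vectors across subjects.
A literal record-level permutation of BMI values would also destroy the
BMI-age relation and the within-subject correlation, i.e. it would test a
broader null than "no genotype effect"; genotype-vector permutation keeps
every trajectory and its covariates intact and targets exactly the
genotype-phenotype null. The literal scheme remains available as
`scheme = "bmi_records"` for comparison. The conventional headline run
uses 10000 permutations; the default is 1000, and the calibration studies
in the test suite use 200.

## Power module

`power_variance_explained()` implements the standard noncentral chi-square
calculation: an effect explaining fraction $R^2$ of trait variance in $n$
subjects gives noncentrality $\lambda = n R^2 / (1 - R^2)$, and power is
the upper-tail probability of $\chi^2_{df}(\lambda)$ beyond the central
critical value. At $n = 658$, $R^2 = 0.023$, $\alpha = 0.05/23 \approx
0.002$ and 1 df this returns 0.808, matching the 80% design benchmark for
this cohort size. The repeated-measures inflation (about 4 observations
per subject) is deliberately *not* folded into this headline number — it
reproduces the plain subject-count calculation — but
`effective_sample_size()` exposes the compound-symmetry adjustment
$n\,m/(1 + (m-1)\,\mathrm{ICC})$ for sensitivity analyses.

## What the synthetic cohort does and does not emulate

`sim_config()` defaults encode the emulated design: 658 subjects with a
308/350 male/female split; birth weight normal at 3.47 kg (male) / 3.33 kg
(female), SD 0.52; gestational age 39.8 (1.8) weeks; visit counts
1 + Poisson with means 4.3 (childhood) and 4.5 (adulthood); visit ages
uniform within stratum ranges; genotypes in Hardy-Weinberg equilibrium at
the 23-SNP panel frequencies; and a BMI trajectory model that mirrors the
analysis model (fixed age/sex/birth-weight effects, configurable SNP main
and interaction effects, correlated random intercept + slope, Gaussian
residuals). Trajectory parameters the design does not pin down were chosen
once at field-plausible values and are stated in `?sim_config`: stratum
intercepts and age slopes placing mean BMI near 17.6 kg/m² mid-childhood
and 28 kg/m² in the thirties, random-intercept SD 2 kg/m², random-slope SD
0.12 kg/m²/yr (correlation 0.2), residual SD 1.5 kg/m².

Known departures from real growth data, and their consequences for what
passing tests show:

* visit ages are drawn independently per visit (no survey-wave spacing);
  the analyses condition on age, not wave, so the tested contracts do not
  depend on spacing;
* simulated SNPs are independent (no linkage disequilibrium), so the
  search's behaviour under correlated candidates is exercised only through
  the burden's own induced correlation, not through LD;
* no dropout, no secular trends, no non-Gaussian BMI tails: calibration
  results (type-I error, permutation uniformity) certify the procedures
  under the model's own assumptions, not robustness to their violation;
* the generative trajectory is linear in age within stratum, matching the
  analysis model rather than challenging it.

Because the individual-level data of the motivating study are not
deposited, its headline real-data numbers (which SNPs were significant,
their q-values, the 14/15-SNP selections, the 2.2%/2.7% variance traces)
are *not* reproduction targets; the package's validation rests on
self-contained design quantities (power, thresholds, heterozygosity) and
on simulation calibration and recovery.

## Problem sizes used in validation

The test suite and the acceptance script run, as the package's chosen
study sizes: 1000 null cohorts of 200 subjects (3 childhood visits) for
scan type-I error; a 1000-replicate 6-of-46 mixture for realized FDR; 100
replicates at the full 658 subjects for effect and interaction recovery
(additive beta 0.5; general age-interaction slopes -0.07/-0.17 per year);
100 search replicates with 5 causal SNPs of 23, each causal variant sized
at roughly the 2%-variance-explained design point (0.7 kg/m² per allele);
100 null cohorts of 80 subjects with 200-permutation searches for
permutation calibration; and a 3-subject toy instance for the brute-force
likelihood oracle. Childhood analyses are the calibration workhorse;
adulthood visits are reduced to one in simulation-heavy studies since only
the childhood stratum is analysed there.

## Limitations

* Gaussian trajectories only; no generalized mixed models, autoregressive
  residuals, or REML mode.
* No population-structure correction: intended for a single homogeneous
  population.
* The burden score is unweighted by construction; weighted scores and
  exhaustive subset search are out of scope.
* Storey's estimator is offered but of limited value at a few dozen tests.
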