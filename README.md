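# longbmi

Longitudinal candidate-SNP association analysis of repeated body mass
index (BMI) measures, for statistical geneticists and epidemiologists
working with growth-cohort designs in which each subject's BMI is measured
several times across childhood (ages 3 to <18) and adulthood (18-45).
The package provides the full toolchain for such a study — genotype QC,
stratified mixed-model SNP scans under dual genetic codings with an FDR
minimum-q rule, SNP×age and SNP×birth-weight interaction tests, a forward
search for a best joint-effect allele-burden model under a modified AIC
with a permutation empirical p-value, and analytic power calculations —
together with a synthetic cohort generator that emulates the design so
every stage is testable without access to individual-level cohort data.

## The model and the search

Longitudinal tests use the linear mixed model, fitted by maximum
likelihood:

    BMI_ij = β0 + βa·age_ij + βs·sex_i + βb·bw_i + g(SNP_i)'γ
             + b0_i + b1_i·age_ij + ε_ij

with a correlated per-subject random intercept and age slope (b0, b1) and
i.i.d. residuals. The genetic term g(·) is a minor-allele dosage
(additive, 1 df), genotype-class indicators against the major-allele
homozygote (general, 2 df), or an unweighted allele burden score. Each SNP
is tested under both codings; q-values are computed per (stratum ×
coding) family and combined per variant as `min(q_additive, q_general)`.

The joint-effect search greedily adds (SNP, reference-allele) pairs to the
burden score, at each step refitting the mixed model with the trial burden
and scoring it with the **modified AIC**

    mAIC = 2·(n_SNP + n_non-SNP) − 2·ln L

which penalises per SNP added (the burden has one coefficient however many
SNPs it sums). The search stops when no candidate strictly reduces the
mAIC; significance of the selected model is assessed by permutation
(genotype vectors permuted across subjects, the full search rerun per
permutation, empirical p = fraction of permuted minimised mAICs at or
below the observed one).

Model fitting uses the package's own compiled profiled-ML engine (fixed
effects and residual variance profiled out in closed form; Nelder-Mead
over the random-effect Cholesky factor), which makes the tens of thousands
of refits behind a permutation run affordable on one CPU; the test suite
verifies it against lme4 and against brute-force multivariate-normal
density evaluation.

## Worked example

Simulate a 658-subject cohort with two injected effects (0.7 and 0.6
kg/m² per minor allele at FTO rs8050136 and BDNF rs6265), scan childhood
BMI, and search for the best joint-effect model:

```r
library(longbmi)

cfg <- sim_config(n_subjects = 658, seed = 42,
                  snp_effects = list(rs8050136 = 0.7, rs6265 = 0.6))
sim <- simulate_cohort(cfg)

scan <- scan_main_effects(sim$cohort, sim$phenotype, stratum = "child")
vq <- summarize_variant_q(scan)
head(vq[order(vq$q_value), ], 4)
#>       snp_id stratum q_additive q_general  q_value
#> 19 rs8050136   child   7.28e-07  8.13e-07 7.28e-07
#> 18 rs1121980   child   1.45e-01  1.45e-01 1.45e-01
#> 12    rs6265   child   1.77e-01  2.91e-01 1.77e-01
#> 15 rs7138803   child   2.43e-01  3.12e-01 2.43e-01

fs <- forward_search(sim$cohort, sim$phenotype, "child")
summary(fs)
#> Forward joint-effect search (child stratum)
#>   covariates-only modified AIC: 11953.452
#>   4 SNPs selected, minimized AIC 11919.793
#>   burden effect: 0.5175 kg/m^2 per reference allele (SE 0.0787)
#>
#> Selection path:
#>  step    snp_id ref_allele modified_aic cum_r2_pct single_r2_pct
#>     1 rs8050136          A        11926      2.445        2.4449
#>     2    rs6265          A        11924      2.809        0.4208
#>     3 rs1121980          T        11922      3.111        0.4920
#>     4 rs7138803          G        11920      3.457        0.3363

permutation_pvalue(sim$cohort, sim$phenotype, "child",
                   n_perm = 200, seed = 1)
#> Permutation test of the best joint-effect model (genotype scheme)
#>   observed minimized AIC: 11919.793
#>   empirical p = 0  (200 permutations)

power_variance_explained(658, 0.023, 0.05 / 23)
#> [1] 0.808
```

The strongest injected effect (rs8050136) dominates the scan
(q = 7.3×10⁻⁷) and is selected first by the search with its risk allele
(A) as reference; the burden model's variance trace grows from 2.4% to
3.5% as weaker contributors join, no permuted search matches the observed
model (empirical p = 0), and the design has 80.8% power for a variant
explaining 2.3% of trait variance at the Bonferroni-adjusted α = 0.05/23.
`plot(fs)` draws the cumulative/single-variant variance trace with
reference alleles per column. See the methods vignette
(`vignettes/longbmi-methods.Rmd`) for the statistical details and design
choices.

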