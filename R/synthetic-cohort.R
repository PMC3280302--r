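#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Builds the configuration object consumed by \code{\link{simulate_cohort}}.
#' The defaults emulate the design of a longitudinal growth cohort of 658
#' subjects (308 male / 350 female), with sex-specific mean birth weights of
#' 3.47 / 3.33 kg (SD 0.52), gestational age 39.8 (SD 1.8) weeks, an average
#' of 4.3 BMI measurements per subject over childhood (ages 3 to <18) and
#' 4.5 over adulthood (18 to 45), genotypes in Hardy-Weinberg equilibrium at
#' the panel allele frequencies, and BMI trajectories driven by fixed age /
#' sex / birth-weight effects plus a correlated per-subject random intercept
#' and age slope and i.i.d. residual noise.
#'
#' Genetic effects are injected through \code{snp_effects} (per-SNP additive
#' beta in kg/m^2 per minor allele, or a length-2 vector
#' \code{c(het, hom)} of genotype-class offsets for a general model),
#' \code{age_interactions} and \code{bw_interactions} (per-SNP slope
#' modifiers per year of age or per kg of birth weight; scalar additive or
#' length-2 general), and \code{bw_genetic_effects} (kg of birth weight per
#' minor allele, for genotype-to-birth-weight paths).
#'
#' @param n_subjects number of subjects.
#' @param snp_panel SNP annotation table (default
#'   \code{\link{default_snp_panel}}).
#' @param sex_ratio fraction male.
#' @param birth_weight_mean_by_sex named vector \code{c(male=, female=)} in kg.
#' @param birth_weight_sd SD of birth weight (kg).
#' @param gestational_age_mean,gestational_age_sd weeks.
#' @param visits_child_mean,visits_adult_mean mean number of visits per
#'   subject and stratum (Poisson, truncated at >= 1).
#' @param child_age_range,adult_age_range visit-age ranges in years.
#' @param baseline_bmi named vector \code{c(child=, adult=)}, kg/m^2
#'   intercepts.
#' @param age_slope named vector \code{c(child=, adult=)}, kg/m^2 per year.
#' @param sex_effect kg/m^2 added for males.
#' @param bw_effect kg/m^2 per kg of birth weight.
#' @param random_intercept_sd,random_slope_sd,random_corr per-subject
#'   random-effect scales (kg/m^2, kg/m^2 per year, correlation).
#' @param residual_sd residual SD (kg/m^2).
#' @param snp_effects,age_interactions,bw_interactions,bw_genetic_effects
#'   named lists keyed by snp_id (see Details).
#' @param seed integer seed making every draw reproducible.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 658L,
                       snp_panel = default_snp_panel(),
                       sex_ratio = 308 / 658,
                       birth_weight_mean_by_sex = c(male = 3.47, female = 3.33),
                       birth_weight_sd = 0.52,
                       gestational_age_mean = 39.8,
                       gestational_age_sd = 1.8,
                       visits_child_mean = 4.3,
                       visits_adult_mean = 4.5,
                       child_age_range = c(3, 18),
                       adult_age_range = c(18, 45),
                       baseline_bmi = c(child = 11.3, adult = 16.6),
                       age_slope = c(child = 0.45, adult = 0.30),
                       sex_effect = 0.5,
                       bw_effect = 0.5,
                       random_intercept_sd = 2.0,
                       random_slope_sd = 0.12,
                       random_corr = 0.2,
                       residual_sd = 1.5,
                       snp_effects = list(),
                       age_interactions = list(),
                       bw_interactions = list(),
                       bw_genetic_effects = list(),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              snp_panel = validate_snp_panel(snp_panel),
              sex_ratio = sex_ratio,
              birth_weight_mean_by_sex = birth_weight_mean_by_sex,
              birth_weight_sd = birth_weight_sd,
              gestational_age_mean = gestational_age_mean,
              gestational_age_sd = gestational_age_sd,
              visits_child_mean = visits_child_mean,
              visits_adult_mean = visits_adult_mean,
              child_age_range = child_age_range,
              adult_age_range = adult_age_range,
              baseline_bmi = baseline_bmi,
              age_slope = age_slope,
              sex_effect = sex_effect,
              bw_effect = bw_effect,
              random_intercept_sd = random_intercept_sd,
              random_slope_sd = random_slope_sd,
              random_corr = random_corr,
              residual_sd = residual_sd,
              snp_effects = snp_effects,
              age_interactions = age_interactions,
              bw_interactions = bw_interactions,
              bw_genetic_effects = bw_genetic_effects,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_subjects >= 1L,
              sex_ratio >= 0, sex_ratio <= 1,
              birth_weight_sd >= 0, gestational_age_sd >= 0,
              visits_child_mean >= 1, visits_adult_mean >= 1,
              random_intercept_sd >= 0, random_slope_sd >= 0,
              abs(random_corr) <= 1, residual_sd >= 0)
    if (child_age_range[2] > 18 || adult_age_range[1] < 18) {
      stop("childhood and adulthood age ranges must be disjoint at 18")
    }
  })
  for (nm in c("snp_effects", "age_interactions", "bw_interactions",
               "bw_genetic_effects")) {
    eff <- cfg[[nm]]
    if (length(eff)) {
      bad <- setdiff(names(eff), cfg$snp_panel$snp_id)
      if (length(bad)) {
        stop(nm, " names not in the panel: ", paste(bad, collapse = ", "))
      }
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate genotype dosages in Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently per subject as Binomial(2, maf), i.e.
#' genotype frequencies (1-p)^2, 2p(1-p), p^2.
#'
#' @param panel SNP annotation table with columns snp_id, maf.
#' @param n number of subjects.
#' @param seed integer seed.
#' @return integer matrix, n x nrow(panel), dosages of the minor allele,
#'   columns named by snp_id.
#' @export
simulate_genotypes <- function(panel, n, seed = 1L) {
  validate_snp_panel(panel)
  stopifnot(n >= 1)
  set.seed(seed)
  G <- vapply(panel$maf, function(p) stats::rbinom(n, 2L, p), integer(n))
  G <- matrix(as.integer(G), nrow = n)
  colnames(G) <- panel$snp_id
  G
}

#' Simulate subject-level covariates
#'
#' Sex by a Bernoulli draw at the configured male fraction; birth weight
#' normal around the sex-specific mean; gestational age normal.  If
#' \code{bw_genetic_effects} are configured and a genotype matrix is given,
#' the per-allele birth-weight shifts are added (a hook for
#' genotype-to-birth-weight interaction studies; birth weight is independent
#' of genotype by default).
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @param genotypes optional dosage matrix for birth-weight genetic effects.
#' @return data frame: subject_id, sex (1 = male, 0 = female), birth_weight
#'   (kg), gestational_age (weeks).
#' @export
simulate_subjects <- function(config, seed = config$seed, genotypes = NULL) {
  set.seed(seed)
  n <- config$n_subjects
  sex <- stats::rbinom(n, 1L, config$sex_ratio)
  mu <- ifelse(sex == 1L, config$birth_weight_mean_by_sex[["male"]],
               config$birth_weight_mean_by_sex[["female"]])
  bw <- stats::rnorm(n, mu, config$birth_weight_sd)
  if (length(config$bw_genetic_effects) && !is.null(genotypes)) {
    for (s in names(config$bw_genetic_effects)) {
      bw <- bw + config$bw_genetic_effects[[s]] * genotypes[, s]
    }
  }
  ga <- stats::rnorm(n, config$gestational_age_mean, config$gestational_age_sd)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)), sex = sex,
             birth_weight = bw, gestational_age = ga,
             stringsAsFactors = FALSE)
}

.genetic_value <- function(eff, dosage) {
  if (length(eff) == 1L) eff * dosage
  else eff[1L] * (dosage == 1L) + eff[2L] * (dosage == 2L)
}

#' Simulate longitudinal BMI trajectories
#'
#' For each subject and stratum, the visit count is 1 + Poisson(mean - 1)
#' and visit ages are uniform on the stratum age range.  BMI is
#' \deqn{baseline_s + slope_s \cdot age + \beta_{sex} sex + \beta_{bw} bw +
#'   \sum_{SNP} genetic(d) + \sum_{SNP} interaction(d) \cdot modifier +
#'   b_{0i} + b_{1i} \cdot age + \epsilon}
#' with per-subject \eqn{(b_0, b_1)} bivariate normal (configured SDs and
#' correlation, shared across both strata of a subject) and i.i.d. normal
#' residuals.
#'
#' @param cohort list with \code{subjects} and \code{genotypes} as produced
#'   by \code{\link{simulate_cohort}} internals.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return data frame: subject_id, age (years), bmi (kg/m^2), stratum
#'   ("child"/"adult").
#' @export
simulate_trajectories <- function(cohort, config, seed = config$seed) {
  set.seed(seed)
  subj <- cohort$subjects
  G <- cohort$genotypes
  n <- nrow(subj)

  ## per-subject random effects, shared across strata
  s1 <- config$random_intercept_sd
  s2 <- config$random_slope_sd
  r <- config$random_corr
  b0 <- stats::rnorm(n, 0, s1)
  b1 <- if (s2 > 0) {
    cond_sd <- s2 * sqrt(max(0, 1 - r^2))
    mu_b1 <- if (s1 > 0) r * s2 / s1 * b0 else 0
    stats::rnorm(n, mu_b1, cond_sd)
  } else rep(0, n)

  one_stratum <- function(stratum, vmean, rng) {
    nv <- 1L + stats::rpois(n, vmean - 1)
    idx <- rep.int(seq_len(n), nv)
    age <- stats::runif(length(idx), rng[1], rng[2])
    ## childhood visits stay strictly below 18
    if (stratum == "child") age <- pmin(age, 18 - 1e-9)
    g_fix <- rep(0, length(idx))
    for (s in names(config$snp_effects)) {
      g_fix <- g_fix + .genetic_value(config$snp_effects[[s]], G[idx, s])
    }
    for (s in names(config$age_interactions)) {
      g_fix <- g_fix +
        .genetic_value(config$age_interactions[[s]], G[idx, s]) * age
    }
    for (s in names(config$bw_interactions)) {
      g_fix <- g_fix + .genetic_value(config$bw_interactions[[s]], G[idx, s]) *
        subj$birth_weight[idx]
    }
    bmi <- config$baseline_bmi[[stratum]] +
      config$age_slope[[stratum]] * age +
      config$sex_effect * subj$sex[idx] +
      config$bw_effect * subj$birth_weight[idx] +
      g_fix + b0[idx] + b1[idx] * age +
      stats::rnorm(length(idx), 0, config$residual_sd)
    data.frame(subject_id = subj$subject_id[idx], age = age, bmi = bmi,
               stratum = stratum, stringsAsFactors = FALSE)
  }

  rbind(one_stratum("child", config$visits_child_mean, config$child_age_range),
        one_stratum("adult", config$visits_adult_mean, config$adult_age_range))
}

#' Simulate a complete cohort
#'
#' Composes \code{\link{simulate_genotypes}}, \code{\link{simulate_subjects}}
#' and \code{\link{simulate_trajectories}} under a single seed and attaches
#' the true-parameter record used, for parameter-recovery testing.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cohort} (subjects, genotypes, snp_panel, truth)
#'   and \code{phenotype} (long-format BMI records).
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  G <- simulate_genotypes(config$snp_panel, config$n_subjects,
                          seed = config$seed)
  subj <- simulate_subjects(config, seed = config$seed + 1L, genotypes = G)
  cohort <- list(subjects = subj, genotypes = G,
                 snp_panel = config$snp_panel,
                 truth = config[c("snp_effects", "age_interactions",
                                  "bw_interactions", "bw_genetic_effects",
                                  "baseline_bmi", "age_slope", "sex_effect",
                                  "bw_effect", "random_intercept_sd",
                                  "random_slope_sd", "random_corr",
                                  "residual_sd", "seed")])
  phen <- simulate_trajectories(cohort, config, seed = config$seed + 2L)
  list(cohort = cohort, phenotype = phen)
}

#' Merge covariates and long phenotype into an analysis frame
#'
#' Joins the subject table onto the long BMI records, optionally restricted
#' to one stratum, producing the observation-level frame the mixed-model
#' functions consume.
#'
#' @param cohort cohort list (subjects, genotypes).
#' @param phenotype long-format phenotype data frame.
#' @param stratum "child", "adult" or NULL for both.
#' @return data frame: subject_id, age, bmi, stratum, sex, birth_weight,
#'   gestational_age.
#' @export
merge_analysis_frame <- function(cohort, phenotype, stratum = NULL) {
  if (!is.null(stratum)) {
    phenotype <- phenotype[phenotype$stratum == stratum, , drop = FALSE]
    if (!nrow(phenotype)) stop("no records in stratum '", stratum, "'")
  }
  i <- match(phenotype$subject_id, cohort$subjects$subject_id)
  if (anyNA(i)) {
    stop("phenotype contains unknown subject ids: ",
         paste(unique(phenotype$subject_id[is.na(i)]), collapse = ", "))
  }
  cbind(phenotype,
        cohort$subjects[i, c("sex", "birth_weight", "gestational_age")],
        row.names = NULL)
}
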