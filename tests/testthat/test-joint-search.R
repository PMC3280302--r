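test_that("a dominant signal is selected alone with its risk allele", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 200, seed = 51,
    snp_effects = list(rs8050136 = 2.0),
    random_intercept_sd = 0.1, random_slope_sd = 0.01,
    residual_sd = 0.1))
  fs <- forward_search(sim$cohort, sim$phenotype, "child")
  expect_equal(fs$trace$snp_id[1], "rs8050136")
  # risk allele (the minor allele carrying the positive effect) is counted
  expect_equal(fs$trace$ref_allele[1], "A")
  expect_gt(fs$burden_beta, 0)
  expect_true(all(diff(c(fs$aic0, fs$trace$modified_aic)) < 0))
})

test_that("a noiseless single-SNP effect is recovered exactly", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 120, seed = 52,
    snp_effects = list(rs1514175 = 0.5),
    sex_effect = 0, bw_effect = 0,
    random_intercept_sd = 0, random_slope_sd = 0, residual_sd = 0))
  fs <- forward_search(sim$cohort, sim$phenotype, "child")
  expect_equal(fs$trace$snp_id[1], "rs1514175")
  expect_equal(fs$burden_beta, 0.5, tolerance = 1e-5)
  be <- burden_effect(fs)
  expect_equal(be$beta, 0.5, tolerance = 1e-5)
})

test_that("allele-flip candidates tie and mirrored burdens share the lnL", {
  sim <- simulate_cohort(sim_config(n_subjects = 150, seed = 53,
                                    snp_effects = list(rs29941 = 0.5)))
  fs <- forward_search(sim$cohort, sim$phenotype, "child")
  # structural first-step tie between the two codings of any SNP
  skip_if(length(fs$selected) == length(fs$panel$snp_id))
  empty <- fs
  empty$selected <- character(0)
  empty$burden_subject <- rep(0, nrow(fs$ctx$Gsub))
  empty$fit <- NULL
  a1 <- evaluate_candidate(empty, "rs2568958", "minor")
  a2 <- evaluate_candidate(empty, "rs2568958", "major")
  expect_equal(a1, a2, tolerance = 1e-6)

  # mirroring every selected reference allele leaves the likelihood alone
  k <- length(fs$selected)
  mirrored <- 2 * k - fs$burden_subject
  ctx <- fs$ctx
  X <- cbind(ctx$X0, burden = mirrored[ctx$idx])
  f2 <- longbmi:::lmm_fit_design(ctx$des, X, ctx$y, "burden")
  expect_equal(f2$logLik, fs$fit$logLik, tolerance = 1e-5)
  expect_equal(f2$coefficients[["burden"]], -fs$burden_beta,
               tolerance = 1e-4)
})

test_that("the accepted path decreases strictly, even under pure noise", {
  for (seed in 1:8) {
    sim <- simulate_cohort(sim_config(n_subjects = 80, seed = 60 + seed,
                                      visits_child_mean = 2))
    fs <- forward_search(sim$cohort, sim$phenotype, "child",
                         compute_r2 = FALSE)
    aics <- c(fs$aic0, fs$trace$modified_aic)
    expect_true(all(diff(aics) < 0))
    expect_lte(fs$min_aic, fs$aic0)
  }
})

test_that("zero-step traces are valid and burden_effect reports missing", {
  sim <- simulate_cohort(sim_config(n_subjects = 40, seed = 77,
                                    visits_child_mean = 1,
                                    residual_sd = 6))
  panel1 <- sim$cohort$snp_panel[1, , drop = FALSE]
  fs <- forward_search(sim$cohort, sim$phenotype, "child", panel = panel1,
                       max_steps = 0)
  expect_equal(nrow(fs$trace), 0L)
  expect_equal(fs$min_aic, fs$aic0)
  expect_true(is.na(burden_effect(fs)$beta))
  expect_error(search_interaction_tests(fs, "age"), "no burden")
})

test_that("permutation p-values are deterministic, granular and signal-sensitive", {
  sim <- simulate_cohort(sim_config(n_subjects = 100, seed = 80,
                                    visits_child_mean = 2))
  panel <- sim$cohort$snp_panel[1:4, ]
  p1 <- permutation_pvalue(sim$cohort, sim$phenotype, "child",
                           panel = panel, n_perm = 30, seed = 7)
  p2 <- permutation_pvalue(sim$cohort, sim$phenotype, "child",
                           panel = panel, n_perm = 30, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$perm_min_aic, p2$perm_min_aic)

  p3 <- permutation_pvalue(sim$cohort, sim$phenotype, "child",
                           panel = panel, n_perm = 1, seed = 3)
  expect_true(p3$p_value %in% c(0, 1))

  # strong joint signal: no permutation should beat the observed model
  sim2 <- simulate_cohort(sim_config(
    n_subjects = 250, seed = 81, visits_child_mean = 2,
    snp_effects = list(rs2568958 = 0.8, rs1514175 = 0.8, rs2867125 = 0.8)))
  p4 <- permutation_pvalue(sim2$cohort, sim2$phenotype, "child",
                           panel = sim2$cohort$snp_panel[1:6, ],
                           n_perm = 50, seed = 11)
  expect_equal(p4$p_value, 0)
})

test_that("burden-by-age interaction on the final model is testable", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 400, seed = 90,
    snp_effects = list(rs8050136 = 0.6, rs1121980 = 0.6)))
  fs <- forward_search(sim$cohort, sim$phenotype, "child")
  skip_if(nrow(fs$trace) == 0)
  it <- search_interaction_tests(fs, "age")
  expect_true(is.finite(it$p_value))
  expect_true(is.finite(it$beta))
})
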