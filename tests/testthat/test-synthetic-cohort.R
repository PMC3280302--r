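test_that("genotype simulation follows the binomial HWE law and the seed", {
  panel <- default_snp_panel()
  expect_equal(nrow(panel), 23L)

  p0 <- panel[1:2, ]
  p0$maf <- c(0, 0.5)
  G <- simulate_genotypes(p0, 10000, seed = 4)
  expect_true(all(G[, 1] == 0))
  maf <- minor_allele_frequency(G[, 2])
  expect_lt(abs(maf - 0.5), 0.015)
  props <- tabulate(G[, 2] + 1L, 3L) / 10000
  expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.02)

  expect_identical(simulate_genotypes(panel, 50, seed = 9),
                   simulate_genotypes(panel, 50, seed = 9))
  bad <- panel
  bad$maf[1] <- 0.7
  expect_error(simulate_genotypes(bad, 10), "\\[0, 0.5\\]")
})

test_that("subject simulation reproduces configured birth-weight structure", {
  cfg <- sim_config(n_subjects = 100000, seed = 21)
  s <- simulate_subjects(cfg)
  expect_lt(abs(mean(s$birth_weight[s$sex == 1]) - 3.47), 0.01)
  expect_lt(abs(mean(s$birth_weight[s$sex == 0]) - 3.33), 0.01)

  cfg0 <- sim_config(n_subjects = 200, birth_weight_sd = 0, seed = 3)
  s0 <- simulate_subjects(cfg0)
  expect_equal(unique(s0$birth_weight[s0$sex == 1]), 3.47)
  expect_equal(unique(s0$birth_weight[s0$sex == 0]), 3.33)

  s1 <- simulate_subjects(sim_config(n_subjects = 50, sex_ratio = 1, seed = 2))
  expect_true(all(s1$sex == 1))
})

test_that("trajectories honour stratum age ranges and visit intensities", {
  sim <- simulate_cohort(sim_config(n_subjects = 400, seed = 31))
  ph <- sim$phenotype
  expect_true(all(ph$age[ph$stratum == "child"] >= 3))
  expect_true(all(ph$age[ph$stratum == "child"] < 18))
  expect_true(all(ph$age[ph$stratum == "adult"] >= 18))
  expect_true(all(ph$age[ph$stratum == "adult"] <= 45))

  # mean childhood visits near 4.3 over replicates
  means <- vapply(1:20, function(k) {
    s <- simulate_cohort(sim_config(n_subjects = 200, seed = 100 + k))
    sum(s$phenotype$stratum == "child") / 200
  }, numeric(1))
  expect_lt(abs(mean(means) - 4.3), 0.2)
})

test_that("noise-free trajectories reproduce the configured fixed effects", {
  cfg <- sim_config(n_subjects = 60, seed = 7,
                    baseline_bmi = c(child = 17.6, adult = 17.6),
                    age_slope = c(child = 0, adult = 0),
                    sex_effect = 0, bw_effect = 0,
                    random_intercept_sd = 0, random_slope_sd = 0,
                    random_corr = 0, residual_sd = 0)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$phenotype$bmi == 17.6))

  cfg2 <- sim_config(n_subjects = 200, seed = 8,
                     snp_effects = list(rs8050136 = 0.5),
                     sex_effect = 0, bw_effect = 0,
                     random_intercept_sd = 0, random_slope_sd = 0,
                     residual_sd = 0,
                     age_slope = c(child = 0.4, adult = 0.4))
  sim2 <- simulate_cohort(cfg2)
  d <- sim2$cohort$genotypes[, "rs8050136"]
  fr <- merge_analysis_frame(sim2$cohort, sim2$phenotype, "child")
  dos <- d[match(fr$subject_id, sim2$cohort$subjects$subject_id)]
  adj <- fr$bmi - 0.4 * fr$age
  for (g in 0:1) {
    if (any(dos == g) && any(dos == g + 1)) {
      expect_equal(mean(adj[dos == g + 1]) - mean(adj[dos == g]), 0.5,
                   tolerance = 1e-10)
    }
  }
})

test_that("slope-only subject variability scales BMI deviations by age", {
  cfg <- sim_config(n_subjects = 800, seed = 17,
                    sex_effect = 0, bw_effect = 0,
                    random_intercept_sd = 0, random_slope_sd = 0.3,
                    random_corr = 0, residual_sd = 0)
  sim <- simulate_cohort(cfg)
  fr <- merge_analysis_frame(sim$cohort, sim$phenotype, "child")
  dev <- (fr$bmi - cfg$baseline_bmi[["child"]] -
            cfg$age_slope[["child"]] * fr$age) / fr$age
  # deviation/age is the subject's random slope: constant within subject
  per_subj <- tapply(dev, fr$subject_id, function(v) diff(range(v)))
  expect_lt(max(per_subj), 1e-8)
  expect_lt(abs(var(tapply(dev, fr$subject_id, mean)) - 0.09), 0.015)
})

test_that("cohort simulation is deterministic and round-trips its truth", {
  cfg <- sim_config(n_subjects = 30, seed = 12,
                    snp_effects = list(rs29941 = 0.4),
                    age_interactions = list(rs6265 = -0.05))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  dir <- tempfile("cohort")
  write_cohort(a, dir)
  back <- read_cohort(dir)
  expect_equal(back$cohort$truth$snp_effects$rs29941, 0.4)
  expect_equal(back$cohort$truth$age_interactions$rs6265, -0.05)
  expect_equal(unname(back$cohort$genotypes), unname(a$cohort$genotypes))
  expect_equal(back$phenotype$bmi, a$phenotype$bmi, tolerance = 1e-9)

  tiny <- simulate_cohort(sim_config(n_subjects = 2, seed = 1))
  expect_s3_class(
    scan <- suppressWarnings(scan_main_effects(tiny$cohort, tiny$phenotype,
                                               "child")),
    "assoc_scan")
})
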