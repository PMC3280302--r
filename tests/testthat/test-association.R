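make_assoc_sim <- function(n = 250, seed = 1, effects = list(), ...) {
  simulate_cohort(sim_config(n_subjects = n, seed = seed,
                             snp_effects = effects, ...))
}

test_that("a strong simulated effect tops the additive childhood scan", {
  sim <- make_assoc_sim(n = 658, seed = 71,
                        effects = list(rs1514175 = 0.8))
  sc <- scan_main_effects(sim$cohort, sim$phenotype, "child")
  add <- sc[sc$coding == "additive", ]
  expect_equal(add$snp_id[which.min(add$p_value)], "rs1514175")
  vq <- summarize_variant_q(sc)
  expect_lte(vq$q_value[vq$snp_id == "rs1514175"], 0.05)
  # the min rule never exceeds either coding's q
  expect_true(all(vq$q_value <= pmin(vq$q_additive, vq$q_general,
                                     na.rm = TRUE) + 1e-12))
})

test_that("the additive test is invariant to which allele is counted", {
  sim <- make_assoc_sim(n = 300, seed = 5,
                        effects = list(rs7138803 = 0.4))
  flipped <- sim
  flipped$cohort$genotypes[, "rs7138803"] <-
    2L - flipped$cohort$genotypes[, "rs7138803"]
  a <- scan_main_effects(sim$cohort, sim$phenotype, "child")
  b <- scan_main_effects(flipped$cohort, flipped$phenotype, "child")
  ia <- a$coding == "additive" & a$snp_id == "rs7138803"
  ib <- b$coding == "additive" & b$snp_id == "rs7138803"
  expect_equal(a$beta[ia], -b$beta[ib], tolerance = 1e-5)
  expect_equal(a$p_value[ia], b$p_value[ib], tolerance = 1e-5)
})

test_that("monomorphic and two-class SNPs degrade gracefully", {
  sim <- make_assoc_sim(n = 150, seed = 9)
  sim$cohort$genotypes[, "rs2568958"] <- 0L          # monomorphic
  sim$cohort$genotypes[, "rs13107325"] <-
    pmin(sim$cohort$genotypes[, "rs13107325"], 1L)   # no minor homozygote
  expect_warning(sc <- scan_main_effects(sim$cohort, sim$phenotype,
                                         "child"),
                 "monomorphic")
  expect_false("rs2568958" %in% sc$snp_id)
  r <- sc[sc$snp_id == "rs13107325", ]
  expect_equal(r$coding, "additive")
  expect_true(all(r$flagged))
})

test_that("genotype effects are re-expressed against the lower-BMI homozygote", {
  # adjusted means (20, 21.5, 21.7) for (AA, AG, GG): baseline AA
  r <- genotype_effects_report(1.5, 1.7, minor_allele = "G",
                               major_allele = "A")
  expect_equal(r$baseline[1], "AA")
  expect_equal(r$effect, c(1.5, 1.7))
  expect_equal(r$genotype, c("AG", "GG"))

  r0 <- genotype_effects_report(0, 0)
  expect_equal(r0$effect, c(0, 0))

  # minor homozygote lower: baseline flips and effects shift
  r2 <- genotype_effects_report(0.5, -1, minor_allele = "G",
                                major_allele = "A")
  expect_equal(r2$baseline[1], "GG")
  expect_equal(r2$effect, c(1.5, 1))
})

test_that("birth-weight scan detects injected effects and flags tiny n", {
  sim <- make_assoc_sim(n = 658, seed = 13,
                        bw_genetic_effects = list(rs1121980 = 0.3))
  bw <- scan_birth_weight(sim$cohort)
  hit <- bw[bw$snp_id == "rs1121980" & bw$coding == "additive", ]
  expect_lte(hit$q_value, 0.05)

  tiny <- make_assoc_sim(n = 5, seed = 3)
  sc <- suppressWarnings(scan_birth_weight(tiny$cohort))
  if (nrow(sc)) expect_true(all(sc$flagged))
})

test_that("null birth weight yields no significant findings (fixed seed)", {
  sim <- make_assoc_sim(n = 658, seed = 29)
  bw <- scan_birth_weight(sim$cohort)
  vq <- summarize_variant_q(bw)
  expect_equal(sum(vq$q_value <= 0.05), 0)
})
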