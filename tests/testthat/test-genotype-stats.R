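test_that("minor allele frequency counts alleles over non-missing calls", {
  expect_equal(minor_allele_frequency(c(0, 0, 0, 0)), 0)
  expect_equal(minor_allele_frequency(c(1, 1, 1, 1)), 0.5)
  # hand count: 4 minor alleles among 10 called chromosomes
  expect_equal(minor_allele_frequency(c(2, 1, 0, 1, 0, NA)), 0.4)
  expect_error(minor_allele_frequency(c(NA, NA)), "missing")
  expect_error(minor_allele_frequency(c(0, 3)), "dosages")
})

test_that("expected heterozygosity is 2pq, symmetric, maximal at 0.5", {
  expect_equal(expected_heterozygosity(0.4), 0.48)
  expect_equal(expected_heterozygosity(0.09), 0.1638)
  expect_equal(expected_heterozygosity(0), 0)
  p <- seq(0, 1, by = 0.05)
  expect_equal(expected_heterozygosity(p), expected_heterozygosity(1 - p))
  expect_equal(max(expected_heterozygosity(p)), 0.5)
  expect_error(expected_heterozygosity(1.2), "\\[0, 1\\]")
})

test_that("observed heterozygosity is the heterozygote fraction", {
  expect_equal(observed_heterozygosity(c(1, 1, 0, 2)), 0.5)
  expect_equal(observed_heterozygosity(c(0, 2, 0, 2)), 0)
  expect_equal(observed_heterozygosity(c(1, 1, 1)), 1)
})

test_that("HWE chi-square matches the Pearson goodness-of-fit oracle", {
  # exact HWE proportions: statistic 0, p = 1
  g <- rep(c(0, 1, 2), c(25, 50, 25))
  r <- hwe_test(g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # (30, 40, 30): Pearson sum over genotype classes at p_hat = 0.5
  g <- rep(c(0, 1, 2), c(30, 40, 30))
  n <- 100
  p_hat <- (2 * 30 + 40) / 200
  exp_counts <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  pearson <- sum((c(30, 40, 30) - exp_counts)^2 / exp_counts)
  r <- hwe_test(g)
  expect_equal(r$statistic, pearson)
  expect_equal(r$p_value, pchisq(pearson, 1, lower.tail = FALSE))

  # maximal violation: all homozygotes, chi-square = n
  r <- hwe_test(rep(c(0, 2), c(50, 50)))
  expect_equal(r$statistic, 100)
  expect_lt(r$p_value, 1e-20)

  expect_error(hwe_test(rep(0, 50)), "monomorphic")
})

test_that("HWE p-values are uniform for genotypes simulated under HWE", {
  n_rep <- 1000
  n <- 658
  p <- 0.3
  set.seed(202)
  rej <- 0
  maf_ok <- 0
  tol <- 4 * sqrt(p * (1 - p) / (2 * n))
  for (i in seq_len(n_rep)) {
    g <- rbinom(n, 2, p)
    if (hwe_test(g)$p_value < 0.05) rej <- rej + 1
    if (abs(minor_allele_frequency(g) - p) < tol) maf_ok <- maf_ok + 1
  }
  # binomial 99% bounds around 0.05 at 1000 replicates
  half <- 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rej / n_rep, 0.05 - half)
  expect_lte(rej / n_rep, 0.05 + half)
  # sample MAF within 4 binomial SDs of truth in >= 99% of replicates
  expect_gte(maf_ok / n_rep, 0.99)
})

test_that("qc_report summarises a panel and flags MAF polarity flips", {
  set.seed(5)
  G <- cbind(snp_a = rbinom(200, 2, 0.3),
             snp_b = rbinom(200, 2, 0.1),
             snp_mono = rep(0L, 200))
  qc <- qc_report(G)
  expect_equal(qc$snp_id, c("snp_a", "snp_b", "snp_mono"))
  expect_equal(qc$n_called, rep(200L, 3))
  expect_true(is.na(qc$hwe_p[3]))
  expect_equal(qc$het_exp, expected_heterozygosity(qc$maf))

  G_flip <- cbind(snp_c = rbinom(40, 2, 0.9))
  expect_warning(qc_report(G_flip), "MAF > 0.5")
})
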