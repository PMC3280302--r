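test_that("noiseless linear data is recovered to numerical precision", {
  set.seed(1)
  sid <- rep(sprintf("S%d", 1:10), each = 3)
  age <- runif(30, 3, 17)
  d <- data.frame(subject_id = sid, age = age, bmi = 17 + 0.5 * age)
  fit <- fit_lmm(bmi ~ age, d)
  expect_equal(unname(coef(fit)), c(17, 0.5), tolerance = 1e-6)
})

test_that("with no random effects the likelihood equals the OLS ML value", {
  d <- make_tiny_frame(n_subjects = 12, visits = 3, seed = 4)
  fit <- fit_lmm(bmi ~ age + sex + birth_weight, d, random = "none")
  ols <- lm(bmi ~ age + sex + birth_weight, d)
  n <- nrow(d)
  s2 <- sum(residuals(ols)^2) / n
  ll_ols <- -0.5 * (n * log(2 * pi * s2) + n)
  expect_equal(fit$logLik, ll_ols, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("engine log-likelihood matches brute-force density evaluation", {
  d <- make_tiny_frame(n_subjects = 3, visits = 4, seed = 11)
  fit <- fit_lmm(bmi ~ age, d)
  G <- matrix(c(fit$varcomp["var_intercept"], fit$varcomp["cov_int_slope"],
                fit$varcomp["cov_int_slope"], fit$varcomp["var_slope"]), 2)
  ll <- mvn_loglik(d$bmi, cbind(1, d$age), coef(fit), d$subject_id, d$age,
                   G, fit$varcomp["var_residual"])
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(42)
  n <- 150
  m <- 4
  sid <- rep(seq_len(n), each = m)
  age <- runif(n * m, 3, 18)
  sex <- rep(rbinom(n, 1, 0.5), each = m)
  bw <- rep(rnorm(n, 3.4, 0.5), each = m)
  dos <- rep(rbinom(n, 2, 0.3), each = m)
  b0 <- rnorm(n, 0, 2)
  b1 <- 0.15 * b0 / 2 + rnorm(n, 0, 0.15)
  bmi <- 14 + 0.4 * age + 0.3 * sex + 0.5 * bw + 0.4 * dos +
    b0[sid] + b1[sid] * age + rnorm(n * m, 0, 1.5)
  d <- data.frame(subject_id = sid, age, sex, birth_weight = bw,
                  dosage = dos, bmi)
  fit <- fit_lmm(bmi ~ age + sex + birth_weight + dosage, d,
                 genetic_terms = "dosage")
  ref <- lme4::lmer(bmi ~ age + sex + birth_weight + dosage +
                      (1 + age | subject_id), d, REML = FALSE)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-3)
})

test_that("log-likelihood is monotone under fixed-effect nesting", {
  for (seed in 1:5) {
    d <- make_tiny_frame(n_subjects = 25, visits = 3, seed = seed)
    small <- fit_lmm(bmi ~ age, d)
    large <- fit_lmm(bmi ~ age + sex + birth_weight + dosage, d,
                     genetic_terms = "dosage")
    expect_gte(large$logLik, small$logLik - 1e-6)
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  d <- make_tiny_frame(n_subjects = 10, visits = 2, seed = 2)
  d$age2 <- 2 * d$age
  expect_error(fit_lmm(bmi ~ age + age2, d), "age2")
})

test_that("fit summaries round-trip through their JSON record", {
  d <- make_tiny_frame(n_subjects = 12, visits = 3, seed = 4)
  fit <- fit_lmm(bmi ~ age + dosage, d, genetic_terms = "dosage")
  path <- tempfile(fileext = ".json")
  write_lmm_fit(fit, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$coefficients$dosage, fit$coefficients[["dosage"]])
  expect_equal(rec$varcomp$var_residual, fit$varcomp[["var_residual"]])
  expect_equal(rec$logLik, fit$logLik)
  expect_equal(rec$genetic_terms, "dosage")
  expect_true(rec$converged)
})

test_that("Wald machinery matches normal-theory reference points", {
  f <- fake_fit(logLik = -10, coefficients = c(x = 1.96),
                vcov = matrix(1, dimnames = list("x", "x")))
  w <- wald_test(f, "x")
  expect_equal(w$p_value, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_equal(w$df, 1L)

  f0 <- fake_fit(logLik = -10, coefficients = c(x = 0),
                 vcov = matrix(2, dimnames = list("x", "x")))
  expect_equal(wald_test(f0, "x")$p_value, 1)

  # diagonal covariance: joint statistic is the sum of 1-df statistics
  V <- diag(c(0.25, 4))
  dimnames(V) <- list(c("a", "b"), c("a", "b"))
  f2 <- fake_fit(logLik = -10, coefficients = c(a = 1, b = 3), vcov = V)
  w2 <- wald_test(f2, c("a", "b"))
  expect_equal(w2$statistic, 1 / 0.25 + 9 / 4)
  expect_equal(w2$df, 2L)
  expect_error(wald_test(f2, "zz"), "not in fit")
})

test_that("modified AIC applies the per-SNP penalty arithmetic", {
  f <- fake_fit(logLik = -100)
  expect_equal(modified_aic(f, n_snps = 3, n_non_snp = 6), 218)
  # one more SNP at unchanged likelihood costs exactly 2
  expect_equal(modified_aic(f, 4, 6) - modified_aic(f, 3, 6), 2)
  # default non-SNP count: non-genetic fixed effects + variance components
  f2 <- fake_fit(logLik = -100, n_fixed = 5, n_varcomp = 4,
                 genetic_terms = "burden")
  expect_equal(modified_aic(f2, 0), 2 * 8 + 200)
  f2$converged <- FALSE
  expect_error(modified_aic(f2, 0), "converged")
})

test_that("marginal R2 matches the variance-decomposition oracle", {
  zero <- fake_fit(logLik = -1)
  zero$genetic_predictor <- rep(0, 100)
  zero$response <- rnorm(100)
  expect_equal(marginal_r2(zero), 0)

  set.seed(6)
  n <- 10000
  p <- 0.3
  b <- 0.5
  d <- rbinom(n, 2, p)
  y <- b * d + rnorm(n, 0, 2)
  dd <- data.frame(subject_id = sprintf("S%d", 1:n), age = runif(n, 3, 18),
                   dosage = d, bmi = y)
  fit <- fit_lmm(bmi ~ dosage, dd, random = "none",
                 genetic_terms = "dosage")
  b_hat <- coef(fit)[["dosage"]]
  # decomposition at the fitted slope: Var(b_hat d) = b_hat^2 2pq
  expect_equal(marginal_r2(fit), 100 * b_hat^2 * 2 * p * (1 - p) / var(y),
               tolerance = 0.05)
  # and consistency with the theoretical effect size at Monte-Carlo error
  expect_equal(marginal_r2(fit), 100 * b^2 * 2 * p * (1 - p) / var(y),
               tolerance = 0.3)

  # a perfect genetic predictor carries all the variance
  dd2 <- dd
  dd2$bmi <- dd2$dosage
  fit2 <- fit_lmm(bmi ~ dosage, dd2, random = "none",
                  genetic_terms = "dosage")
  expect_equal(marginal_r2(fit2), 100, tolerance = 1e-6)
})
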