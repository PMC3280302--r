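# Independent oracles and small fixture builders shared across tests.

# Brute-force Gaussian log-likelihood: builds the full marginal covariance
# V = Z G Z' + sigma2 I per subject block and evaluates the multivariate
# normal density directly.  Used to validate the profiled-likelihood
# engine; shares no code with it.
mvn_loglik <- function(y, X, beta, subject, age, G, sigma2,
                       random = "intercept_slope") {
  ll <- 0
  r <- y - drop(X %*% beta)
  for (s in unique(subject)) {
    i <- which(subject == s)
    Zi <- if (random == "intercept_slope") cbind(1, age[i]) else
      cbind(age[i])
    Vi <- Zi %*% G %*% t(Zi) + sigma2 * diag(length(i))
    ri <- r[i]
    ll <- ll - 0.5 * (length(i) * log(2 * pi) +
                        determinant(Vi, logarithm = TRUE)$modulus +
                        drop(t(ri) %*% solve(Vi, ri)))
  }
  as.numeric(ll)
}

# Tiny longitudinal frame with known structure, for exactness tests.
make_tiny_frame <- function(n_subjects = 3, visits = 2, seed = 11,
                            residual_sd = 1, b_sd = c(1, 0.1), corr = 0.3) {
  set.seed(seed)
  sid <- rep(sprintf("S%02d", seq_len(n_subjects)), each = visits)
  age <- runif(n_subjects * visits, 4, 17)
  sex <- rep(rbinom(n_subjects, 1, 0.5), each = visits)
  bw <- rep(rnorm(n_subjects, 3.4, 0.5), each = visits)
  dosage <- rep(rbinom(n_subjects, 2, 0.3), each = visits)
  Sg <- diag(b_sd) %*% matrix(c(1, corr, corr, 1), 2) %*% diag(b_sd)
  L <- chol(Sg)
  b <- matrix(rnorm(2 * n_subjects), n_subjects) %*% L
  i <- rep(seq_len(n_subjects), each = visits)
  bmi <- 14 + 0.4 * age + 0.3 * sex + 0.5 * bw + 0.2 * dosage +
    b[i, 1] + b[i, 2] * age + rnorm(length(age), 0, residual_sd)
  data.frame(subject_id = sid, age = age, sex = sex, birth_weight = bw,
             dosage = dosage, bmi = bmi, stringsAsFactors = FALSE)
}

# A minimal converged fit-like object for arithmetic-only tests.
fake_fit <- function(logLik, n_fixed = 5, n_varcomp = 4,
                     genetic_terms = "burden",
                     coefficients = c(burden = 1), vcov = matrix(1, 1, 1,
                       dimnames = list("burden", "burden"))) {
  structure(list(coefficients = coefficients,
                 se = sqrt(diag(vcov)), vcov = vcov,
                 logLik = logLik, n_fixed = n_fixed,
                 n_varcomp = n_varcomp, genetic_terms = genetic_terms,
                 converged = TRUE),
            class = "lmm_fit")
}
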