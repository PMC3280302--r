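#' Fit the longitudinal linear mixed model by maximum likelihood
#'
#' Fits a Gaussian linear mixed model for repeated BMI measures with a
#' per-subject random effect of age, by maximum likelihood (never REML, so
#' that log-likelihoods of models differing in fixed effects are comparable
#' and usable in information criteria).  The random structure is either a
#' correlated random intercept and age slope per subject (default, an
#' unstructured 2x2 covariance), a random age slope only, or no random
#' effects (ordinary least squares).
#'
#' Estimation profiles the fixed effects and the residual variance out of the
#' likelihood in closed form and optimises the profiled deviance over the
#' Cholesky factor of the relative random-effect covariance, the standard
#' parameterisation for this model class.  The optimiser is deterministic
#' (Nelder-Mead with a fixed start, plus one polishing restart).
#'
#' @param formula model formula for the fixed effects, e.g.
#'   \code{bmi ~ age + sex + birth_weight + dosage}.  All terms must be
#'   columns of \code{data}.
#' @param data data frame with one row per observation (long format).
#' @param subject name of the column identifying subjects (default
#'   \code{"subject_id"}).
#' @param age_var name of the column giving the measurement age in years,
#'   used as the random-slope regressor (default \code{"age"}).
#' @param genetic_terms character vector naming the coefficient(s) of the
#'   design matrix that are genetic (dosage, genotype indicators, burden
#'   score, or their interaction products).  Used for parameter bookkeeping
#'   in \code{\link{modified_aic}} and for \code{\link{marginal_r2}}.
#' @param random random-effects structure: \code{"intercept_slope"}
#'   (default), \code{"slope"}, or \code{"none"}.
#' @param start optional numeric start for the relative-covariance Cholesky
#'   parameters (length 3 for \code{"intercept_slope"}, 1 for
#'   \code{"slope"}); used to warm-start refits in scans and searches.
#' @return an object of class \code{"lmm_fit"}: coefficients, standard
#'   errors, coefficient covariance, variance components (random-intercept
#'   variance, random-slope variance, their covariance, residual variance),
#'   the maximised log-likelihood, counts of observations/subjects/
#'   parameters, and a convergence flag.
#' @examples
#' cfg <- sim_config(n_subjects = 80, seed = 1)
#' sim <- simulate_cohort(cfg)
#' d <- merge_analysis_frame(sim$cohort, sim$phenotype, stratum = "child")
#' d$dosage <- sim$cohort$genotypes[match(d$subject_id, sim$cohort$subjects$subject_id), 1]
#' fit <- fit_lmm(bmi ~ age + sex + birth_weight + dosage, d,
#'                genetic_terms = "dosage")
#' coef(fit)
#' @export
fit_lmm <- function(formula, data, subject = "subject_id", age_var = "age",
                    genetic_terms = character(0),
                    random = c("intercept_slope", "slope", "none"),
                    start = NULL) {
  random <- match.arg(random)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!subject %in% names(data)) {
    stop("subject column '", subject, "' not found in data")
  }
  if (nrow(X) != nrow(data)) {
    stop("model frame dropped rows; remove missing values before fitting")
  }

  ## rank check with named collinear columns, before any heavy work
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  sid <- data[[subject]]
  if (length(unique(sid)) < 2L) stop("need at least 2 subjects")
  missing_g <- setdiff(genetic_terms, colnames(X))
  if (length(missing_g)) {
    stop("genetic_terms not in design: ", paste(missing_g, collapse = ", "))
  }

  if (random == "none") {
    fit <- .fit_ols(y, X, sid, genetic_terms, formula)
    return(fit)
  }

  age <- data[[age_var]]
  if (is.null(age)) stop("age column '", age_var, "' not found")
  des <- lmm_design(sid, age, random)
  fit <- lmm_fit_design(des, X, y, genetic_terms, start = start)
  fit$formula <- formula
  fit
}

## Grouped-design descriptor reused across many fits on the same
## observations (scans, forward search, permutation null): row order and
## subject block boundaries are computed once.
lmm_design <- function(subject_id, age, random = "intercept_slope") {
  ord <- order(match(subject_id, unique(subject_id)))
  so <- subject_id[ord]
  runs <- rle(as.character(so))
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])   # 0-based for C++
  ao <- age[ord]
  Z <- if (random == "intercept_slope") cbind(1, ao) else cbind(ao)
  list(ord = ord, starts = as.integer(starts), ends = as.integer(ends),
       Z = Z, random = random, n_subjects = length(ends),
       default_theta = if (random == "intercept_slope") c(1, 0, 1) else 1)
}

## Low-level ML fit on an explicit design matrix; rows ordered as in `data`
## passed to lmm_design (reordering happens here, once).
lmm_fit_design <- function(des, X, y, genetic_terms = character(0),
                           start = NULL, reltol = 1e-12, maxit = 1000L) {
  if (is.null(start)) start <- des$default_theta
  Xo <- X[des$ord, , drop = FALSE]
  yo <- y[des$ord]
  sol <- lmm_fit_cpp(Xo, des$Z, yo, des$starts, des$ends, start,
                     reltol, maxit, 1L)
  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  vc <- sol$vcov
  dimnames(vc) <- list(colnames(X), colnames(X))
  G <- sol$G
  varcomp <- if (des$random == "intercept_slope") {
    c(var_intercept = G[1, 1], var_slope = G[2, 2], cov_int_slope = G[1, 2],
      var_residual = sol$sigma2)
  } else {
    c(var_slope = G[1, 1], var_residual = sol$sigma2)
  }
  gpred <- if (length(genetic_terms)) {
    drop(X[, genetic_terms, drop = FALSE] %*% beta[genetic_terms])
  } else NULL
  structure(list(
    coefficients = beta,
    se = sqrt(diag(vc)),
    vcov = vc,
    varcomp = varcomp,
    fitted = drop(X %*% beta),
    logLik = -sol$deviance / 2,
    deviance = sol$deviance,
    theta = drop(sol$theta),
    n_obs = length(y),
    n_subjects = des$n_subjects,
    n_fixed = ncol(X),
    n_varcomp = length(varcomp),
    genetic_terms = genetic_terms,
    genetic_predictor = gpred,
    response = y,
    random = des$random,
    converged = isTRUE(sol$converged),
    formula = NULL
  ), class = "lmm_fit")
}

.fit_ols <- function(y, X, sid, genetic_terms, formula) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n                 # ML variance, to keep lnL comparable
  ll <- -0.5 * (n * log(2 * pi * sigma2) + n)
  XtXi <- chol2inv(chol(crossprod(X)))
  vc <- sigma2 * XtXi
  dimnames(vc) <- list(colnames(X), colnames(X))
  beta <- fit$coefficients
  gpred <- if (length(genetic_terms)) {
    drop(X[, genetic_terms, drop = FALSE] %*% beta[genetic_terms])
  } else NULL
  structure(list(
    coefficients = beta, se = sqrt(diag(vc)), vcov = vc,
    varcomp = c(var_residual = sigma2),
    fitted = drop(X %*% beta),
    logLik = ll, deviance = -2 * ll, theta = numeric(0),
    n_obs = n, n_subjects = length(unique(sid)),
    n_fixed = ncol(X), n_varcomp = 1L,
    genetic_terms = genetic_terms, genetic_predictor = gpred,
    response = y, random = "none", converged = TRUE, formula = formula
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML)")
  if (!isTRUE(x$converged)) cat("  [NOT CONVERGED]")
  cat("\n  formula: ", deparse(x$formula), "\n", sep = "")
  cat("  ", x$n_obs, " observations, ", x$n_subjects, " subjects, random = ",
      x$random, "\n", sep = "")
  cat("  logLik:", format(x$logLik, digits = 6), "\n\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.lmm_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, varcomp = object$varcomp,
              logLik = object$logLik, n_obs = object$n_obs,
              n_subjects = object$n_subjects, formula = object$formula,
              converged = object$converged)
  class(out) <- "summary.lmm_fit"
  out
}

#' @export
print.summary.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML):", deparse(x$formula), "\n")
  cat(x$n_obs, "observations,", x$n_subjects, "subjects; logLik",
      format(x$logLik, digits = 6), "\n\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nVariance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$coefficients

#' @export
fitted.lmm_fit <- function(object, ...) object$fitted

#' @export
residuals.lmm_fit <- function(object, ...) {
  ## marginal residuals: response minus the fixed-effect prediction
  object$response - object$fitted
}

#' @export
vcov.lmm_fit <- function(object, ...) object$vcov

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$logLik,
            df = object$n_fixed + object$n_varcomp,
            nobs = object$n_obs, class = "logLik")
}

#' Serialize a fit summary as JSON
#'
#' Writes the estimates of a converged fit — coefficients, standard
#' errors, variance components, log-likelihood, counts and the
#' convergence flag — as a JSON record.
#'
#' @param fit an \code{\link{fit_lmm}} object.
#' @param path output file path.
#' @export
write_lmm_fit <- function(fit, path) {
  rec <- list(coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              varcomp = as.list(fit$varcomp),
              logLik = fit$logLik,
              n_obs = fit$n_obs, n_subjects = fit$n_subjects,
              n_fixed = fit$n_fixed, n_varcomp = fit$n_varcomp,
              genetic_terms = fit$genetic_terms,
              random = fit$random,
              converged = fit$converged)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Joint Wald test on named coefficients
#'
#' Computes the joint Wald chi-square statistic for the hypothesis that all
#' named coefficients are zero, with degrees of freedom equal to the number
#' of terms tested.
#'
#' @param fit an \code{\link{fit_lmm}} object (or any object with
#'   \code{coef} and \code{vcov} methods).
#' @param terms character vector of coefficient names to test jointly.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
wald_test <- function(fit, terms) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  miss <- setdiff(terms, names(b))
  if (length(miss)) stop("terms not in fit: ", paste(miss, collapse = ", "))
  bi <- b[terms]
  Vi <- V[terms, terms, drop = FALSE]
  Vinv <- tryCatch(solve(Vi), error = function(e) NULL)
  if (is.null(Vinv)) stop("singular coefficient covariance for Wald test")
  stat <- drop(t(bi) %*% Vinv %*% bi)
  df <- length(terms)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Modified AIC with a per-SNP penalty
#'
#' The model-selection score used by the forward joint-effect search:
#' \deqn{2 (n_{SNP} + n_{non-SNP}) - 2 \ln L}
#' where \eqn{n_{SNP}} is the number of SNPs contributing to the burden
#' score (not the number of estimated genetic coefficients — a burden model
#' has one coefficient regardless of how many SNPs it sums, which is what
#' makes the criterion "modified") and \eqn{n_{non-SNP}} counts all other
#' estimated parameters: the non-genetic fixed effects plus the variance
#' components.
#'
#' @param fit a converged \code{\link{fit_lmm}} object.
#' @param n_snps number of SNPs in the genetic term.
#' @param n_non_snp optional override for the non-SNP parameter count; by
#'   default derived from the fit as (fixed coefficients that are not
#'   genetic terms) + (variance components).
#' @return the modified AIC (smaller is better).
#' @export
modified_aic <- function(fit, n_snps, n_non_snp = NULL) {
  if (!isTRUE(fit$converged)) stop("modified_aic requires a converged fit")
  if (is.null(n_non_snp)) {
    n_non_snp <- (fit$n_fixed - length(fit$genetic_terms)) + fit$n_varcomp
  }
  2 * (n_snps + n_non_snp) - 2 * fit$logLik
}

#' Share of phenotypic variance carried by the genetic predictor
#'
#' For a fitted model with genetic fixed effects, returns
#' \eqn{100 \cdot Var(\hat\beta_g S) / Var(y)} over observations: the
#' percentage of total observed phenotype variance attributable to the
#' fitted genetic fixed-effect predictor \eqn{S} (a dosage, genotype
#' indicators, or a burden score).  A constant predictor gives 0.
#'
#' @param fit a converged \code{\link{fit_lmm}} with genetic terms.
#' @param predictor optional numeric vector overriding the stored genetic
#'   fixed-effect predictor (one value per observation).
#' @return percentage in [0, 100] (can exceed 100 only in pathological
#'   overfit cases).
#' @export
marginal_r2 <- function(fit, predictor = NULL) {
  if (!isTRUE(fit$converged)) stop("marginal_r2 requires a converged fit")
  g <- if (is.null(predictor)) fit$genetic_predictor else predictor
  if (is.null(g)) stop("fit has no genetic predictor")
  vg <- stats::var(g)
  if (!is.finite(vg) || vg == 0) return(0)
  100 * vg / stats::var(fit$response)
}
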