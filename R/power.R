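#' Bonferroni per-test significance threshold
#'
#' @param alpha_family family-wise error rate.
#' @param m number of tests.
#' @return per-test alpha = alpha_family / m.
#' @export
bonferroni_threshold <- function(alpha_family, m) {
  if (m < 1) stop("number of tests must be >= 1")
  alpha_family / m
}

#' Power for a variance-explained quantitative-trait effect
#'
#' Analytic power of a chi-square association test for an effect explaining
#' a given fraction of trait variance: with \eqn{R^2} the variance
#' explained and n subjects, the noncentrality is
#' \eqn{\lambda = n R^2 / (1 - R^2)} and power is the probability that a
#' noncentral \eqn{\chi^2_{df}(\lambda)} exceeds the central critical value
#' at level alpha.  With df = 1 this is the standard design calculation for
#' an additive single-variant test; it uses the subject count, not the
#' inflated repeated-measures observation count (see
#' \code{\link{effective_sample_size}} for that adjustment).
#'
#' @param n number of subjects (>= 2).
#' @param variance_explained fraction of trait variance in (0, 1).
#' @param alpha per-test type-I error in (0, 1).
#' @param df test degrees of freedom (1 for the additive coding).
#' @return power in [0, 1].
#' @export
power_variance_explained <- function(n, variance_explained, alpha, df = 1) {
  if (n < 2 || variance_explained <= 0 || variance_explained >= 1 ||
      alpha <= 0 || alpha >= 1 || df < 1) {
    stop("invalid power query")
  }
  lambda <- n * variance_explained / (1 - variance_explained)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE)
}

#' Smallest variance-explained detectable at a target power
#'
#' Inverts \code{\link{power_variance_explained}} by bisection on the
#' variance-explained fraction.
#'
#' @inheritParams power_variance_explained
#' @param target_power power to reach, in (0, 1).
#' @return variance-explained fraction whose power is within about 1e-6 of
#'   the target.
#' @export
minimum_detectable_r2 <- function(n, alpha, target_power, df = 1) {
  if (target_power <= 0 || target_power >= 1) {
    stop("target power must be in (0, 1)")
  }
  if (target_power <= alpha) return(0)
  f <- function(r2) power_variance_explained(n, r2, alpha, df) - target_power
  upper <- 1 - 1e-9
  if (f(upper) < 0) stop("target power unreachable at this n and alpha")
  stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
}

#' Effective sample size for repeated measures
#'
#' Repeated measurements inflate the observation count; under a
#' compound-symmetry working model the information of n subjects with m
#' measurements each at intraclass correlation ICC equals that of
#' \eqn{n m / (1 + (m - 1) ICC)} independent subjects.  Provided as a
#' separate adjustment: the headline design calculation deliberately uses
#' the plain subject count.
#'
#' @param n subjects.
#' @param m measurements per subject.
#' @param icc intraclass correlation in [0, 1].
#' @return effective number of independent subjects.
#' @export
effective_sample_size <- function(n, m, icc) {
  stopifnot(n >= 1, m >= 1, icc >= 0, icc <= 1)
  n * m / (1 + (m - 1) * icc)
}
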