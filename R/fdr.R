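#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted q-values: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)}/j},
#' clipped at 1, returned in the input order.  This is the deterministic
#' default engine for the scan q-values (computed through
#' \code{stats::p.adjust}, which implements exactly this formula).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bh_qvalues <- function(p) {
  .check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with smoothed pi0 estimation
#'
#' Estimates the null proportion pi0 from the flat right tail of the
#' p-value distribution over a lambda grid, pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)), smoothed by a natural cubic spline
#' and evaluated at the largest lambda, then scales the Benjamini-Hochberg
#' step-up values by pi0.  With \code{pi0 = 1} forced, the result is
#' identical to \code{\link{bh_qvalues}}.  A degenerate estimate
#' (pi0 <= 0, as can happen in tiny families) falls back to 1 with a
#' warning.
#'
#' @param p numeric vector of p-values in [0, 1]; families of at least 10
#'   tests are recommended for a stable pi0.
#' @param lambda_grid grid of tail cutoffs in [0, 1).
#' @param pi0 optional fixed null proportion overriding estimation.
#' @return list with \code{qvalues} and the \code{pi0} used.
#' @export
storey_qvalues <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  .check_pvalues(p)
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l),
                    numeric(1))
    pi0 <- if (length(lambda_grid) >= 4L) {
      sp <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
      stats::predict(sp, x = max(lambda_grid))$y
    } else {
      min(pi0_l)
    }
    if (!is.finite(pi0) || pi0 <= 0) {
      warning("degenerate pi0 estimate; falling back to pi0 = 1")
      pi0 <- 1
    }
    pi0 <- min(pi0, 1)
  }
  list(qvalues = pmin(pi0 * stats::p.adjust(p, method = "BH"), 1), pi0 = pi0)
}

.check_pvalues <- function(p) {
  if (!length(p)) stop("empty p-value family")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  invisible(p)
}

#' Combine dual-coding q-values by the minimum rule
#'
#' Per variant, the q-value is the smaller of the additive-coding and
#' general-coding q-values (each already FDR-adjusted within its own
#' coding family); with only one coding available, that q-value is used.
#'
#' @param q_additive,q_general numeric vectors (NA where a coding is
#'   unavailable), aligned by variant.
#' @return per-variant summary q-values.
#' @export
min_qvalue <- function(q_additive, q_general) {
  stopifnot(length(q_additive) == length(q_general))
  pmin(ifelse(is.na(q_additive), Inf, q_additive),
       ifelse(is.na(q_general), Inf, q_general)) |>
    (\(q) ifelse(is.finite(q), q, NA_real_))()
}
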