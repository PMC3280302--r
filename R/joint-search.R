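#' Heuristic forward search for the best joint-effect burden model
#'
#' Greedy forward selection of SNPs (and, per SNP, of the counted
#' "reference" allele) into an unweighted allele burden score — the
#' per-subject sum of reference-allele copies over the selected SNPs — used
#' as a single genetic covariate of the longitudinal mixed model
#' \code{bmi ~ age + sex + birth_weight + burden}.  At each step every
#' (remaining SNP x allele) candidate is refitted and scored by the
#' modified AIC, \code{2 (n_SNP + n_non-SNP) - 2 lnL}
#' (\code{\link{modified_aic}}); the minimum-AIC candidate is accepted if it
#' strictly improves on the current model, and the search stops when no
#' candidate does.  The step-0 reference is the covariates-only model.
#'
#' Candidates whose trial burden is constant (or whose fit fails) are
#' unavailable.  Ties in AIC within 1e-8 — including the structural tie at
#' the first step, where the two allele codings of a SNP span the same
#' model space — are broken by preferring the allele whose fitted burden
#' coefficient is positive (the risk-allele reporting convention), then the
#' lower panel index.  Missing dosages are mean-imputed per SNP inside the
#' burden only, so the score is defined for every subject.
#'
#' @param cohort cohort list (subjects, genotypes, snp_panel).
#' @param phenotype long-format BMI records.
#' @param stratum "child" or "adult".
#' @param panel optional subset of the cohort's SNP panel to search over.
#' @param random random-effects structure.
#' @param max_steps optional cap on accepted steps (used by scaled-down
#'   calibration studies; the default searches to the AIC stopping rule).
#' @param compute_r2 if TRUE (default) the trace carries the cumulative
#'   burden variance share and each selected SNP's single-variant share
#'   (one extra fit per accepted SNP).
#' @return object of class \code{"joint_search"}: \code{trace} (one row per
#'   accepted step: step, snp_id, ref_allele, modified_aic, cum_r2_pct,
#'   single_r2_pct), \code{aic0}, \code{min_aic}, the final \code{fit},
#'   \code{burden_beta}/\code{burden_se}, and the subject-level burden.
#' @export
forward_search <- function(cohort, phenotype, stratum,
                           panel = cohort$snp_panel,
                           random = "intercept_slope",
                           max_steps = Inf, compute_r2 = TRUE) {
  ctx <- .search_context(cohort, phenotype, stratum, panel, random)
  res <- .search_core(ctx, ctx$Gsub, max_steps, compute_r2)
  res$stratum <- stratum
  res$panel <- panel
  res$ctx <- ctx
  res
}

## Precompute everything reusable across searches on the same observations
## (the permutation null reuses this with permuted genotype rows).
.search_context <- function(cohort, phenotype, stratum, panel, random) {
  frame <- merge_analysis_frame(cohort, phenotype, stratum)
  sid <- cohort$subjects$subject_id
  G <- cohort$genotypes[, panel$snp_id, drop = FALSE]
  ## mean-impute per SNP (subject level) so the burden is always defined
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[!nas, j])
  }
  idx <- match(frame$subject_id, sid)
  X0 <- cbind(`(Intercept)` = 1, age = frame$age, sex = frame$sex,
              birth_weight = frame$birth_weight)
  des <- lmm_design(frame$subject_id, frame$age, random)
  fit0 <- lmm_fit_design(des, X0, frame$bmi)
  n_non_snp <- ncol(X0) + fit0$n_varcomp
  list(frame = frame, Gsub = G, idx = idx, X0 = X0, y = frame$bmi,
       des = des, fit0 = fit0, n_non_snp = n_non_snp, panel = panel,
       random = random)
}

## Slim candidate fit used in the search hot loop: one warm-started C++
## call, no fit object construction.  The burden is always the last design
## column.
.fit_burden_fast <- function(des, Xb, y_ord, warm) {
  sol <- lmm_fit_cpp(Xb, des$Z, y_ord, des$starts, des$ends, warm,
                     1e-10, 1000L, 0L)
  if (!isTRUE(sol$converged)) return(NULL)
  list(dev = sol$deviance, coef = sol$beta[length(sol$beta)],
       theta = drop(sol$theta))
}

.search_core <- function(ctx, Gsub, max_steps = Inf, compute_r2 = TRUE) {
  des <- ctx$des
  X0 <- ctx$X0
  y <- ctx$y
  idx <- ctx$idx
  n_non_snp <- ctx$n_non_snp
  snps <- colnames(Gsub)
  aic0 <- 2 * n_non_snp - 2 * ctx$fit0$logLik

  ## pre-ordered buffers for the hot loop (rows grouped by subject)
  Xb <- cbind(X0, burden = 0)[des$ord, , drop = FALSE]
  bcol <- ncol(Xb)
  y_ord <- y[des$ord]
  idx_ord <- idx[des$ord]

  selected <- character(0)
  ref_allele <- character(0)
  alleles <- character(0)
  burden_sub <- rep(0, nrow(Gsub))
  cur_aic <- aic0
  cur_dev_fit <- NULL
  theta <- ctx$fit0$theta
  trace <- list()
  EPS <- 1e-8

  eval_fast <- function(trial_sub, warm) {
    b <- trial_sub[idx_ord]
    if (stats::var(b) < .Machine$double.eps) return(NULL)
    Xb[, bcol] <- b
    .fit_burden_fast(des, Xb, y_ord, warm)
  }

  repeat {
    if (length(selected) >= max_steps) break
    remaining <- setdiff(snps, selected)
    if (!length(remaining)) break
    first_step <- length(selected) == 0L

    best <- NULL
    for (pi in seq_along(remaining)) {
      s <- remaining[pi]
      d_min <- Gsub[, s]
      codings <- if (first_step) list(minor = d_min) else
        list(minor = d_min, major = 2 - d_min)
      for (al in names(codings)) {
        trial_sub <- burden_sub + codings[[al]]
        f <- eval_fast(trial_sub, theta)
        if (is.null(f)) next
        k <- length(selected) + 1L
        aic <- 2 * (k + n_non_snp) + f$dev
        cand <- list(snp = s, allele = al, aic = aic,
                     burden_sub = trial_sub, coef = f$coef,
                     theta = f$theta, order = pi)
        if (first_step && f$coef < 0) {
          ## structural allele-flip tie: the mirrored coding has the same
          ## lnL; re-express with the positive-effect allele as reference
          cand$allele <- "major"
          cand$burden_sub <- burden_sub + 2 - d_min
          cand$coef <- -f$coef
        }
        if (is.null(best) || aic < best$aic - EPS) {
          best <- cand
        } else if (aic < best$aic + EPS) {
          ## AIC tie: prefer positive burden coefficient, then panel order
          better <- (cand$coef > 0 && best$coef <= 0) ||
            (sign(cand$coef) == sign(best$coef) && cand$order < best$order)
          if (better) best <- cand
        }
      }
    }

    if (is.null(best) || best$aic >= cur_aic - 0) break  # strict improvement
    allele_letter <- ctx$panel[ctx$panel$snp_id == best$snp,
                               if (best$allele == "minor") "minor_allele"
                               else "major_allele"]
    selected <- c(selected, best$snp)
    ref_allele <- c(ref_allele, allele_letter)
    alleles <- c(alleles, best$allele)
    burden_sub <- best$burden_sub
    cur_aic <- best$aic
    theta <- best$theta

    single_r2 <- NA_real_
    cum_r2 <- NA_real_
    if (compute_r2) {
      X <- cbind(X0, burden = burden_sub[idx])
      fstep <- lmm_fit_design(des, X, y, "burden", start = theta)
      if (isTRUE(fstep$converged)) cum_r2 <- marginal_r2(fstep)
      d_single <- if (best$allele == "minor") Gsub[, best$snp] else
        2 - Gsub[, best$snp]
      if (stats::var(d_single[idx]) > .Machine$double.eps) {
        Xs <- cbind(X0, burden = d_single[idx])
        fs <- lmm_fit_design(des, Xs, y, "burden", start = theta)
        if (isTRUE(fs$converged)) single_r2 <- marginal_r2(fs)
      }
    }
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), snp_id = best$snp,
      ref_allele = allele_letter, modified_aic = cur_aic,
      cum_r2_pct = cum_r2, single_r2_pct = single_r2,
      stringsAsFactors = FALSE)
  }

  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), snp_id = character(0),
               ref_allele = character(0), modified_aic = numeric(0),
               cum_r2_pct = numeric(0), single_r2_pct = numeric(0))
  has_steps <- nrow(trace_df) > 0L
  final_fit <- NULL
  if (has_steps) {
    X <- cbind(X0, burden = burden_sub[idx])
    final_fit <- lmm_fit_design(des, X, y, "burden", start = theta)
  }
  structure(list(
    trace = trace_df,
    aic0 = aic0,
    min_aic = if (has_steps) cur_aic else aic0,
    fit = final_fit,
    fit0 = ctx$fit0,
    burden_beta = if (has_steps) final_fit$coefficients[["burden"]] else NA_real_,
    burden_se = if (has_steps) final_fit$se[["burden"]] else NA_real_,
    burden_subject = burden_sub,
    selected = selected, ref_allele = ref_allele,
    n_non_snp = ctx$n_non_snp
  ), class = "joint_search")
}

#' Modified AIC of one trial burden candidate
#'
#' Scores the addition of one (SNP, allele) pair to the current burden: the
#' trial burden adds that allele's copy count to the selected burden, the
#' mixed model is refitted with the trial burden as its single genetic
#' covariate, and the modified AIC is returned with the SNP count increased
#' by one.  A constant trial burden (or a failed fit) is unavailable and
#' scores \code{Inf}.
#'
#' @param search a \code{"joint_search"} object (its context carries the
#'   design and covariates).
#' @param snp SNP id not yet selected.
#' @param allele "minor" or "major": which allele's copies to count.
#' @return the candidate's modified AIC (\code{Inf} if unavailable).
#' @export
evaluate_candidate <- function(search, snp, allele = c("minor", "major")) {
  allele <- match.arg(allele)
  ctx <- search$ctx
  if (is.null(ctx)) stop("search object carries no context")
  if (snp %in% search$selected) stop("SNP ", snp, " already selected")
  if (!snp %in% colnames(ctx$Gsub)) stop("SNP ", snp, " not in panel")
  d <- ctx$Gsub[, snp]
  if (allele == "major") d <- 2 - d
  trial <- (search$burden_subject + d)[ctx$idx]
  if (stats::var(trial) < .Machine$double.eps) return(Inf)
  X <- cbind(ctx$X0, burden = trial)
  f <- lmm_fit_design(ctx$des, X, ctx$y, "burden",
                      start = if (!is.null(search$fit)) search$fit$theta)
  if (!isTRUE(f$converged)) return(Inf)
  2 * (length(search$selected) + 1L + search$n_non_snp) - 2 * f$logLik
}

#' Final burden-score effect
#'
#' The fitted coefficient of the burden score in the final joint-effect
#' model: the estimated BMI change per additional copy of a reference
#' allele, with its standard error and Wald p-value.
#'
#' @param search a \code{"joint_search"} object with at least one accepted
#'   step.
#' @return list with \code{beta}, \code{se}, \code{p_value}, \code{n_snps}.
#' @export
burden_effect <- function(search) {
  if (!nrow(search$trace)) {
    return(list(beta = NA_real_, se = NA_real_, p_value = NA_real_,
                n_snps = 0L))
  }
  w <- wald_test(search$fit, "burden")
  list(beta = search$burden_beta, se = search$burden_se,
       p_value = w$p_value, n_snps = length(search$selected))
}

#' Permutation empirical p-value for the best joint-effect model
#'
#' Generates the null distribution of the minimized modified AIC by
#' severing the genotype-phenotype link and rerunning the full forward
#' search (including allele selection) per permutation.  The default
#' scheme permutes whole subject genotype vectors across subjects, keeping
#' every BMI trajectory and its covariates intact — this targets exactly
#' the genotype-phenotype null while preserving the within-subject
#' correlation and the BMI-age/covariate structure.  A literal
#' record-level BMI permutation is available as \code{scheme =
#' "bmi_records"} for comparison; it additionally destroys the BMI-age
#' relation and is not the default for that reason.
#'
#' The empirical p-value is the fraction of permutations whose minimized
#' AIC is less than or equal to the observed minimized AIC.
#'
#' @inheritParams forward_search
#' @param n_perm number of permutations (the headline analysis convention
#'   is 10000; calibration studies use hundreds).
#' @param seed integer seed (all permutations derive from it).
#' @param scheme "genotype" (default) or "bmi_records".
#' @param max_steps optional cap forwarded to the searches.
#' @return list of class \code{"perm_test"}: \code{p_value},
#'   \code{observed_min_aic}, \code{perm_min_aic} (vector), \code{n_perm},
#'   \code{seed}, and the observed \code{search}.
#' @export
permutation_pvalue <- function(cohort, phenotype, stratum,
                               panel = cohort$snp_panel, n_perm = 1000L,
                               seed = 1L, scheme = c("genotype",
                                                     "bmi_records"),
                               random = "intercept_slope",
                               max_steps = Inf) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1L)
  obs <- forward_search(cohort, phenotype, stratum, panel, random,
                        max_steps = max_steps, compute_r2 = FALSE)
  ctx <- obs$ctx
  n_sub <- nrow(ctx$Gsub)

  set.seed(seed)
  perm_aic <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (scheme == "genotype") {
      Gp <- ctx$Gsub[sample.int(n_sub), , drop = FALSE]
      res <- .search_core(ctx, Gp, max_steps = max_steps,
                          compute_r2 = FALSE)
    } else {
      ctx_b <- ctx
      ctx_b$y <- ctx$y[sample.int(length(ctx$y))]
      ctx_b$fit0 <- lmm_fit_design(ctx$des, ctx$X0, ctx_b$y)
      res <- .search_core(ctx_b, ctx$Gsub, max_steps = max_steps,
                          compute_r2 = FALSE)
    }
    perm_aic[b] <- res$min_aic
  }
  structure(list(p_value = mean(perm_aic <= obs$min_aic),
                 observed_min_aic = obs$min_aic, perm_min_aic = perm_aic,
                 n_perm = n_perm, seed = seed, scheme = scheme,
                 search = obs),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test of the best joint-effect model (", x$scheme,
      " scheme)\n", sep = "")
  cat(sprintf("  observed minimized AIC: %.3f\n", x$observed_min_aic))
  cat(sprintf("  empirical p = %.4g  (%d permutations)\n", x$p_value,
              x$n_perm))
  invisible(x)
}

#' Interaction of the final burden score with age or birth weight
#'
#' Adds a burden x modifier product to the final joint-effect model and
#' reports its coefficient (the change of the per-allele burden effect per
#' year of age or per kg of birth weight) with a Wald p-value.
#'
#' @param search a \code{"joint_search"} with at least one accepted step.
#' @param modifier "age" or "birth_weight".
#' @return list with \code{beta}, \code{se}, \code{p_value}.
#' @export
search_interaction_tests <- function(search,
                                     modifier = c("age", "birth_weight")) {
  modifier <- match.arg(modifier)
  if (!nrow(search$trace)) stop("search accepted no SNPs; no burden model")
  ctx <- search$ctx
  if (is.null(ctx)) stop("search object carries no context")
  mod <- ctx$frame[[modifier]]
  if (stats::var(mod) == 0) {
    stop("modifier '", modifier, "' is constant: product collinear ",
         "with the burden main effect")
  }
  burden_obs <- search$burden_subject[ctx$idx]
  X <- cbind(ctx$X0, burden = burden_obs, burden_x_mod = burden_obs * mod)
  f <- lmm_fit_design(ctx$des, X, ctx$y, c("burden", "burden_x_mod"),
                      start = search$fit$theta)
  w <- wald_test(f, "burden_x_mod")
  list(beta = f$coefficients[["burden_x_mod"]],
       se = f$se[["burden_x_mod"]], p_value = w$p_value, fit = f)
}

#' @export
print.joint_search <- function(x, ...) {
  cat("Forward joint-effect search (", x$stratum, " stratum)\n", sep = "")
  cat(sprintf("  covariates-only modified AIC: %.3f\n", x$aic0))
  if (!nrow(x$trace)) {
    cat("  no SNP improved the modified AIC; empty model\n")
    return(invisible(x))
  }
  cat(sprintf("  %d SNPs selected, minimized AIC %.3f\n",
              nrow(x$trace), x$min_aic))
  cat(sprintf("  burden effect: %.4f kg/m^2 per reference allele (SE %.4f)\n",
              x$burden_beta, x$burden_se))
  invisible(x)
}

#' @export
summary.joint_search <- function(object, ...) {
  print(object)
  if (nrow(object$trace)) {
    cat("\nSelection path:\n")
    print(object$trace, digits = 4, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.joint_search <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::coef(object$fit)
}

#' Variance-explained trace plot of a forward search
#'
#' Plots the cumulative percentage of BMI variance explained by the burden
#' score after each accepted SNP (solid) and each SNP's single-variant
#' percentage (dashed), with the reference allele printed above each
#' column.
#'
#' @param x a \code{"joint_search"} object fitted with
#'   \code{compute_r2 = TRUE}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.joint_search <- function(x, ...) {
  tr <- x$trace
  if (!nrow(tr)) {
    warning("empty search trace; nothing to plot")
    return(invisible(x))
  }
  ylim <- range(0, tr$cum_r2_pct, tr$single_r2_pct, na.rm = TRUE)
  graphics::plot(tr$step, tr$cum_r2_pct, type = "o", pch = 16,
                 ylim = ylim * c(1, 1.15), xaxt = "n",
                 xlab = "Sequentially added SNP",
                 ylab = "% BMI variance explained", ...)
  graphics::lines(tr$step, tr$single_r2_pct, lty = 2, type = "o", pch = 1)
  graphics::axis(1, at = tr$step, labels = tr$snp_id, las = 2,
                 cex.axis = 0.7)
  graphics::text(tr$step, ylim[2] * 1.1, tr$ref_allele, cex = 0.8)
  graphics::legend("topleft", legend = c("cumulative", "single variant"),
                   lty = c(1, 2), pch = c(16, 1), bty = "n")
  invisible(x)
}
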