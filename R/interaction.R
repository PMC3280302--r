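#' Test modification of a SNP effect by age or birth weight
#'
#' Augments the longitudinal main-effect mixed model with genotype x
#' modifier product terms and jointly Wald-tests the products.  Under the
#' general coding (default) the products are heterozygote x modifier and
#' minor-homozygote x modifier against the major-allele-homozygote
#' baseline, giving the reported \code{beta1} (effect change of the
#' heterozygote per unit modifier: per year of age, or per kg of birth
#' weight) and \code{beta2} (effect change of the reference-allele
#' homozygote per unit modifier); the additive coding uses a single
#' dosage x modifier product.  All main effects (genotype, age, sex, birth
#' weight) are retained; the age and birth-weight covariates stay in the
#' model regardless of which of them is the modifier.
#'
#' @param cohort cohort list (subjects, genotypes, snp_panel).
#' @param phenotype long-format BMI records.
#' @param snp SNP id to test.
#' @param stratum "child" or "adult".
#' @param modifier "age" or "birth_weight".
#' @param coding "general" (default) or "additive"; a SNP with a missing
#'   genotype class is tested under the additive coding with a flag.
#' @param random random-effects structure.
#' @return list of class \code{"interaction_test"}: snp_id, stratum,
#'   modifier, reference allele, coding used, beta1/beta2 (general) or
#'   beta (additive) with SEs, joint Wald p-value, flag.
#' @export
test_interaction <- function(cohort, phenotype, snp, stratum,
                             modifier = c("age", "birth_weight"),
                             coding = c("general", "additive"),
                             random = "intercept_slope") {
  modifier <- match.arg(modifier)
  coding <- match.arg(coding)
  frame <- merge_analysis_frame(cohort, phenotype, stratum)
  d_obs <- cohort$genotypes[match(frame$subject_id,
                                  cohort$subjects$subject_id), snp]
  keep <- !is.na(d_obs)
  fr <- frame[keep, , drop = FALSE]
  d <- d_obs[keep]
  classes <- sort(unique(d))
  if (length(classes) < 2L) stop("SNP ", snp, " is monomorphic")

  mod <- fr[[modifier]]
  if (stats::var(mod) == 0) {
    stop("modifier '", modifier, "' is constant: the product term is ",
         "collinear with the genotype main effect")
  }

  flagged <- FALSE
  if (coding == "general" && length(classes) < 3L) {
    coding <- "additive"
    flagged <- TRUE
  }

  if (coding == "general") {
    het <- as.numeric(d == 1)
    hom <- as.numeric(d == 2)
    X <- cbind(`(Intercept)` = 1, age = fr$age, sex = fr$sex,
               birth_weight = fr$birth_weight, het = het, hom = hom,
               het_x_mod = het * mod, hom_x_mod = hom * mod)
    gen_terms <- c("het", "hom", "het_x_mod", "hom_x_mod")
    test_terms <- c("het_x_mod", "hom_x_mod")
  } else {
    X <- cbind(`(Intercept)` = 1, age = fr$age, sex = fr$sex,
               birth_weight = fr$birth_weight, dosage = d,
               dosage_x_mod = d * mod)
    gen_terms <- c("dosage", "dosage_x_mod")
    test_terms <- "dosage_x_mod"
  }

  des <- lmm_design(fr$subject_id, fr$age, random)
  fit <- lmm_fit_design(des, X, fr$bmi, gen_terms)
  if (!isTRUE(fit$converged)) {
    return(structure(list(snp_id = snp, stratum = stratum,
                          modifier = modifier, converged = FALSE),
                     class = "interaction_test"))
  }
  w <- wald_test(fit, test_terms)

  panel_row <- cohort$snp_panel[cohort$snp_panel$snp_id == snp, ]
  out <- list(snp_id = snp, stratum = stratum, modifier = modifier,
              reference_allele = panel_row$minor_allele,
              coding = coding, flagged = flagged,
              p_value = w$p_value, df = w$df, fit = fit, converged = TRUE)
  if (coding == "general") {
    out$beta1 <- fit$coefficients[["het_x_mod"]]
    out$se1 <- fit$se[["het_x_mod"]]
    out$beta2 <- fit$coefficients[["hom_x_mod"]]
    out$se2 <- fit$se[["hom_x_mod"]]
  } else {
    out$beta <- fit$coefficients[["dosage_x_mod"]]
    out$se <- fit$se[["dosage_x_mod"]]
  }
  structure(out, class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat("SNP x ", x$modifier, " interaction: ", x$snp_id, " (", x$stratum,
      " stratum)\n", sep = "")
  if (!isTRUE(x$converged)) {
    cat("  model did not converge\n")
    return(invisible(x))
  }
  if (x$coding == "general") {
    cat(sprintf("  beta1 (het)  = %.4f (SE %.4f)\n", x$beta1, x$se1))
    cat(sprintf("  beta2 (hom)  = %.4f (SE %.4f)\n", x$beta2, x$se2))
  } else {
    cat(sprintf("  beta (per allele) = %.4f (SE %.4f)\n", x$beta, x$se))
  }
  cat(sprintf("  joint Wald p = %.3g (%d df)\n", x$p_value, x$df))
  invisible(x)
}

#' Interaction scan across the SNP panel
#'
#' Applies \code{\link{test_interaction}} to every SNP under both codings,
#' computes q-values per (stratum x modifier x coding) family, and combines
#' codings per variant by the minimum-q rule.
#'
#' @inheritParams test_interaction
#' @param fdr "bh" or "storey".
#' @return data frame: snp_id, stratum, modifier, reference_allele, coding,
#'   beta1, beta2 (general rows), beta (additive rows), p_value, q_value,
#'   plus a per-variant min-q summary in attribute \code{"variant_q"}.
#' @export
scan_interactions <- function(cohort, phenotype, stratum,
                              modifier = c("age", "birth_weight"),
                              fdr = c("bh", "storey"),
                              random = "intercept_slope") {
  modifier <- match.arg(modifier)
  fdr <- match.arg(fdr)
  rows <- list()
  for (s in cohort$snp_panel$snp_id) {
    for (cod in c("additive", "general")) {
      r <- tryCatch(
        test_interaction(cohort, phenotype, s, stratum, modifier,
                         coding = cod, random = random),
        error = function(e) NULL)
      if (is.null(r) || !isTRUE(r$converged)) next
      if (cod == "general" && r$coding == "additive") next  # class missing
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, stratum = stratum, modifier = modifier,
        reference_allele = r$reference_allele, coding = r$coding,
        beta1 = if (r$coding == "general") r$beta1 else NA_real_,
        beta2 = if (r$coding == "general") r$beta2 else NA_real_,
        beta = if (r$coding == "additive") r$beta else NA_real_,
        p_value = r$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (cod in unique(out$coding)) {
    i <- out$coding == cod
    out$q_value[i] <- if (fdr == "bh") bh_qvalues(out$p_value[i]) else
      storey_qvalues(out$p_value[i])$qvalues
  }
  key <- unique(out$snp_id)
  getq <- function(snp, cod) {
    i <- out$snp_id == snp & out$coding == cod
    if (any(i)) out$q_value[which(i)[1L]] else NA_real_
  }
  qa <- vapply(key, getq, numeric(1), cod = "additive")
  qg <- vapply(key, getq, numeric(1), cod = "general")
  attr(out, "variant_q") <- data.frame(snp_id = key, q_additive = qa,
                                       q_general = qg,
                                       q_value = min_qvalue(qa, qg),
                                       row.names = NULL)
  out
}
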