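#' Single-SNP main-effect scan of longitudinal BMI
#'
#' For every SNP in the panel, fits the longitudinal mixed model
#' \code{bmi ~ age + sex + birth_weight + genetic term} (random intercept +
#' age slope per subject, ML) twice within the chosen stratum: once under
#' the additive coding (minor-allele dosage, 1-df Wald test) and once under
#' the general coding (heterozygote and minor-homozygote indicators against
#' the major-homozygote baseline, joint 2-df Wald test).  SNPs with a
#' missing genotype class are tested under the additive coding only and
#' flagged; monomorphic SNPs are skipped with a warning.  q-values are
#' computed per (stratum x coding) family and combined per variant by the
#' minimum rule (\code{\link{summarize_variant_q}}).
#'
#' @param cohort cohort list with \code{subjects}, \code{genotypes},
#'   \code{snp_panel}.
#' @param phenotype long-format BMI records (subject_id, age, bmi, stratum).
#' @param stratum "child" or "adult".
#' @param fdr FDR engine for q-values: "bh" (default) or "storey".
#' @param random random-effects structure passed to the fitter.
#' @return data frame of class \code{"assoc_scan"}: one row per SNP and
#'   coding with effect estimates, standard errors, Wald p, family q,
#'   observation/subject counts and a flag for reduced codings.
#' @export
scan_main_effects <- function(cohort, phenotype, stratum,
                              fdr = c("bh", "storey"),
                              random = "intercept_slope") {
  fdr <- match.arg(fdr)
  frame <- merge_analysis_frame(cohort, phenotype, stratum)
  rows <- .scan_genetic(frame, cohort, stratum, longitudinal = TRUE,
                        random = random)
  .finish_scan(rows, fdr)
}

#' Cross-sectional birth-weight scan
#'
#' Ordinary linear model \code{birth_weight ~ genetic term +
#' gestational_age + sex} per SNP, under both codings, with q-values per
#' coding family.  With very few subjects the fit is returned but flagged
#' as having unreliable degrees of freedom.
#'
#' @inheritParams scan_main_effects
#' @return data frame of class \code{"assoc_scan"} with stratum
#'   \code{"birthweight"}.
#' @export
scan_birth_weight <- function(cohort, fdr = c("bh", "storey")) {
  fdr <- match.arg(fdr)
  frame <- cohort$subjects
  frame$subject_id <- cohort$subjects$subject_id
  rows <- .scan_genetic(frame, cohort, "birthweight", longitudinal = FALSE)
  .finish_scan(rows, fdr)
}

.scan_genetic <- function(frame, cohort, stratum, longitudinal,
                          random = "intercept_slope") {
  G <- cohort$genotypes
  panel <- cohort$snp_panel
  sid <- cohort$subjects$subject_id

  rows <- list()
  for (s in panel$snp_id) {
    d_obs <- G[match(frame$subject_id, sid), s]
    keep <- !is.na(d_obs)
    fr <- frame[keep, , drop = FALSE]
    d <- d_obs[keep]
    classes <- sort(unique(d))
    if (length(classes) < 2L) {
      warning("SNP ", s, " is monomorphic in stratum ", stratum,
              "; skipped")
      next
    }
    full_general <- length(classes) == 3L
    n_obs <- nrow(fr)
    n_subj <- length(unique(fr$subject_id))

    fit_one <- function(gen_cols, gen_names) {
      if (longitudinal) {
        X <- cbind(`(Intercept)` = 1, age = fr$age, sex = fr$sex,
                   birth_weight = fr$birth_weight, gen_cols)
        colnames(X)[5:(4 + length(gen_names))] <- gen_names
        des <- lmm_design(fr$subject_id, fr$age, random)
        lmm_fit_design(des, X, fr$bmi, gen_names)
      } else {
        X <- cbind(`(Intercept)` = 1, gestational_age = fr$gestational_age,
                   sex = fr$sex, gen_cols)
        colnames(X)[4:(3 + length(gen_names))] <- gen_names
        .fit_ols(fr$birth_weight, X, fr$subject_id, gen_names, NULL)
      }
    }

    ## additive coding
    add_row <- tryCatch({
      add <- fit_one(cbind(d), "dosage")
      if (!isTRUE(add$converged)) stop("no convergence")
      w <- wald_test(add, "dosage")
      if (!is.finite(w$p_value)) stop("degenerate test")
      data.frame(
        snp_id = s, stratum = stratum, coding = "additive",
        beta = add$coefficients[["dosage"]], se = add$se[["dosage"]],
        beta_het = NA_real_, se_het = NA_real_,
        beta_hom = NA_real_, se_hom = NA_real_,
        p_value = w$p_value, n_obs = n_obs, n_subjects = n_subj,
        flagged = !full_general || (!longitudinal && n_subj < 10L),
        stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (!is.null(add_row)) rows[[length(rows) + 1L]] <- add_row

    ## general coding needs all three genotype classes
    if (full_general) {
      gen_row <- tryCatch({
        gen <- fit_one(cbind(het = as.numeric(d == 1),
                             hom = as.numeric(d == 2)), c("het", "hom"))
        if (!isTRUE(gen$converged)) stop("no convergence")
        w <- wald_test(gen, c("het", "hom"))
        if (!is.finite(w$p_value)) stop("degenerate test")
        data.frame(
          snp_id = s, stratum = stratum, coding = "general",
          beta = NA_real_, se = NA_real_,
          beta_het = gen$coefficients[["het"]], se_het = gen$se[["het"]],
          beta_hom = gen$coefficients[["hom"]], se_hom = gen$se[["hom"]],
          p_value = w$p_value, n_obs = n_obs, n_subjects = n_subj,
          flagged = (!longitudinal && n_subj < 10L),
          stringsAsFactors = FALSE)
      }, error = function(e) NULL)
      if (!is.null(gen_row)) rows[[length(rows) + 1L]] <- gen_row
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.finish_scan <- function(rows, fdr) {
  if (is.null(rows)) {
    return(structure(data.frame(), class = c("assoc_scan", "data.frame")))
  }
  rows$q_value <- NA_real_
  for (cod in unique(rows$coding)) {
    i <- rows$coding == cod
    q <- if (fdr == "bh") bh_qvalues(rows$p_value[i]) else
      storey_qvalues(rows$p_value[i])$qvalues
    rows$q_value[i] <- q
  }
  rownames(rows) <- NULL
  structure(rows, class = c("assoc_scan", "data.frame"))
}

#' Per-variant minimum q-value across codings
#'
#' Applies the dual-coding rule: the q-value of a variant is the smaller of
#' its additive-model and general-model q-values (each FDR-adjusted within
#' its own coding family); when only one coding was testable, its q-value
#' is used.
#'
#' @param scan an \code{"assoc_scan"} data frame.
#' @return data frame with snp_id, stratum, q_additive, q_general, q_value.
#' @export
summarize_variant_q <- function(scan) {
  if (!nrow(scan)) return(data.frame())
  key <- unique(scan[, c("snp_id", "stratum")])
  get_q <- function(snp, stratum, cod) {
    i <- scan$snp_id == snp & scan$stratum == stratum & scan$coding == cod
    if (any(i)) scan$q_value[which(i)[1L]] else NA_real_
  }
  qa <- mapply(get_q, key$snp_id, key$stratum, "additive")
  qg <- mapply(get_q, key$snp_id, key$stratum, "general")
  data.frame(key, q_additive = unname(qa), q_general = unname(qg),
             q_value = min_qvalue(qa, qg), row.names = NULL)
}

#' Genotype-effect report relative to the lower-BMI homozygote
#'
#' Re-expresses general-model genotype effects with the homozygote having
#' the lower adjusted mean as baseline, the convention used when reporting
#' per-genotype effect pairs: returns the heterozygote effect and the other
#' homozygote's effect above that baseline.  This is a reporting transform
#' only; model fitting always uses the major-allele homozygote as baseline.
#'
#' @param beta_het,beta_hom general-model coefficients of the heterozygote
#'   and minor-allele homozygote against the major-homozygote baseline.
#' @param minor_allele,major_allele single-letter allele labels.
#' @return data frame with the baseline genotype label and the two effects
#'   (genotype label, effect vs baseline).
#' @export
genotype_effects_report <- function(beta_het, beta_hom,
                                    minor_allele = "A", major_allele = "B") {
  hom_major <- paste0(major_allele, major_allele)
  hom_minor <- paste0(minor_allele, minor_allele)
  het <- paste0(major_allele, minor_allele)
  if (beta_hom >= 0) {
    data.frame(baseline = hom_major,
               genotype = c(het, hom_minor),
               effect = c(beta_het, beta_hom), stringsAsFactors = FALSE)
  } else {
    data.frame(baseline = hom_minor,
               genotype = c(het, hom_major),
               effect = c(beta_het - beta_hom, -beta_hom),
               stringsAsFactors = FALSE)
  }
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat("Association scan:", nrow(x), "tests\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a scan result as TSV
#'
#' @param scan an \code{"assoc_scan"} data frame.
#' @param path output file path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
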