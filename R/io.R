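#' Read a genotype dosage table
#'
#' The canonical genotype store is a tab-separated table: one header row of
#' SNP ids after a leading \code{subject_id} column, one row per subject,
#' cells 0/1/2 (minor-allele dosage) or NA.  Any other cell value is a
#' parse error reported with its row and column; duplicated subject ids
#' are rejected.
#'
#' @param path file path.
#' @return numeric matrix subjects x SNPs with subject ids as row names.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "subject_id") {
    stop("first column must be 'subject_id'")
  }
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  G <- as.matrix(tab[, -1, drop = FALSE])
  mode(G) <- "numeric"
  bad <- which(!(is.na(G) | G %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-dosage cell at row %d (subject %s), column %s",
                 bad[1, 1], ids[bad[1, 1]], colnames(G)[bad[1, 2]]))
  }
  rownames(G) <- ids
  G
}

#' @rdname read_genotypes
#' @param genotypes dosage matrix with subject row names.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file (convenience)
#'
#' Converts VCF genotype calls to minor-allele dosages against a SNP panel:
#' for each panel SNP found in the VCF, ALT-allele counts are taken from
#' the GT field; when the VCF REF allele is the panel's minor allele (i.e.
#' REF/ALT are swapped relative to the panel polarity), dosages are flipped
#' to count the panel's minor allele, with a message.  Requires the vcfR
#' package.
#'
#' @param path VCF file path.
#' @param panel SNP annotation table giving each SNP's minor/major allele.
#' @return numeric dosage matrix, subjects x panel SNPs found in the file.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  validate_snp_panel(panel)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  keep <- ids %in% panel$snp_id
  if (!any(keep)) stop("no panel SNPs found in VCF")
  out <- matrix(NA_real_, ncol(gt), sum(keep),
                dimnames = list(colnames(gt), ids[keep]))
  for (j in which(keep)) {
    s <- ids[j]
    row <- panel[panel$snp_id == s, ]
    alt_count <- vapply(gt[j, ], function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(gsub("\\|", "/", g), "/")[[1]]
      sum(al == "1")
    }, numeric(1))
    if (fix[j, "ALT"] == row$minor_allele) {
      out[, s] <- alt_count
    } else if (fix[j, "REF"] == row$minor_allele) {
      message("VCF REF/ALT swapped relative to panel minor allele for ", s,
              "; dosages flipped")
      out[, s] <- 2 - alt_count
    } else {
      warning("VCF alleles for ", s, " do not match the panel; SNP dropped")
      out <- out[, colnames(out) != s, drop = FALSE]
    }
  }
  out
}

#' Read a long-format phenotype table
#'
#' Tab-separated columns subject_id, age (years), bmi (kg/m^2).  The
#' stratum is derived from age: under 18 years is childhood, 18 or older is
#' adulthood.  Ages outside [0, 120] or non-positive BMI values are
#' rejected, as are subject ids absent from the supplied roster.
#'
#' @param path file path.
#' @param subject_ids optional character vector of known subject ids.
#' @return data frame subject_id, age, bmi, stratum.
#' @export
read_phenotypes <- function(path, subject_ids = NULL) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "age", "bmi")
  miss <- setdiff(req, names(ph))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(ph$age)) || any(ph$age < 0) || any(ph$age > 120)) {
    stop("age values must lie in [0, 120] years")
  }
  if (any(!is.finite(ph$bmi)) || any(ph$bmi <= 0)) {
    stop("bmi values must be positive")
  }
  if (!is.null(subject_ids)) {
    unknown <- setdiff(ph$subject_id, subject_ids)
    if (length(unknown)) {
      stop("unknown subject ids in phenotype table: ",
           paste(unknown, collapse = ", "))
    }
  }
  ph$stratum <- ifelse(ph$age < 18, "child", "adult")
  ph[, c("subject_id", "age", "bmi", "stratum")]
}

#' @rdname read_phenotypes
#' @param phenotype long-format phenotype data frame.
#' @export
write_phenotypes <- function(phenotype, path) {
  utils::write.table(phenotype[, c("subject_id", "age", "bmi", "stratum")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the subject covariate table
#'
#' Tab-separated columns subject_id, sex (1 male / 0 female), birth_weight
#' (kg), gestational_age (weeks).
#'
#' @param path file path.
#' @export
read_subjects <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "sex", "birth_weight", "gestational_age")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("subject table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(s$subject_id)) stop("duplicated subject ids")
  s
}

#' @rdname read_subjects
#' @param subjects subject covariate data frame.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a simulated cohort directory
#'
#' A cohort round-trips through four plain-text files: subjects.tsv,
#' genotypes.tsv, phenotypes.tsv and truth.json (the true simulation
#' parameters, for recovery studies).
#'
#' @param sim list with \code{cohort} and \code{phenotype}
#'   (\code{\link{simulate_cohort}} output).
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_subjects(sim$cohort$subjects, file.path(dir, "subjects.tsv"))
  G <- sim$cohort$genotypes
  rownames(G) <- sim$cohort$subjects$subject_id
  write_genotypes(G, file.path(dir, "genotypes.tsv"))
  write_phenotypes(sim$phenotype, file.path(dir, "phenotypes.tsv"))
  write_snp_panel(sim$cohort$snp_panel, file.path(dir, "snp_panel.tsv"))
  jsonlite::write_json(sim$cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- read_subjects(file.path(dir, "subjects.tsv"))
  G <- read_genotypes(file.path(dir, "genotypes.tsv"))
  phen <- read_phenotypes(file.path(dir, "phenotypes.tsv"),
                          subject_ids = subjects$subject_id)
  panel <- read_snp_panel(file.path(dir, "snp_panel.tsv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(cohort = list(subjects = subjects, genotypes = G,
                     snp_panel = panel, truth = truth),
       phenotype = phen)
}

#' Read a simulation configuration file
#'
#' Accepts a JSON or YAML file whose keys are \code{\link{sim_config}}
#' arguments (unknown keys are rejected); list-valued effect entries
#' (snp_effects etc.) are passed through.  YAML input requires the yaml
#' package.
#'
#' @param path file path ending in .json, .yaml or .yml.
#' @return a validated \code{"sim_config"} object.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configuration requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml")
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in c("birth_weight_mean_by_sex", "baseline_bmi", "age_slope")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("snp_effects", "age_interactions", "bw_interactions",
               "bw_genetic_effects")) {
    if (!is.null(raw[[nm]])) {
      raw[[nm]] <- lapply(raw[[nm]], function(x) unlist(x))
    }
  }
  do.call(sim_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, on a simulated or loaded cohort: genotype QC, the main-effect
#' scans (childhood, adulthood, birth weight), the interaction scans, the
#' forward joint-effect search per stratum with its permutation test, and
#' the design power summary, writing every table under \code{out_dir}
#' stamped with the seed.  Identical configuration and seed give identical
#' outputs.
#'
#' @param sim cohort list as from \code{\link{simulate_cohort}} or
#'   \code{\link{read_cohort}}; if NULL, a cohort is simulated from
#'   \code{config}.
#' @param config a \code{\link{sim_config}} used when \code{sim} is NULL.
#' @param out_dir output directory; NULL skips writing.
#' @param n_perm permutations for the joint-search empirical p-value.
#' @param seed seed for the permutation draws.
#' @param fdr FDR engine, "bh" or "storey".
#' @param strata strata to analyse.
#' @return list with qc, scans, interactions, searches, permutation tests
#'   and the power summary.
#' @export
run_pipeline <- function(sim = NULL, config = sim_config(),
                         out_dir = NULL, n_perm = 200L, seed = 1L,
                         fdr = "bh", strata = c("child", "adult")) {
  if (is.null(sim)) sim <- simulate_cohort(config)
  cohort <- sim$cohort
  phen <- sim$phenotype

  qc <- qc_report(cohort$genotypes)

  scans <- list()
  interactions <- list()
  searches <- list()
  perms <- list()
  for (st in strata) {
    scans[[st]] <- scan_main_effects(cohort, phen, st, fdr = fdr)
    interactions[[paste0(st, "_age")]] <-
      scan_interactions(cohort, phen, st, "age", fdr = fdr)
    interactions[[paste0(st, "_bw")]] <-
      scan_interactions(cohort, phen, st, "birth_weight", fdr = fdr)
    perms[[st]] <- permutation_pvalue(cohort, phen, st, n_perm = n_perm,
                                      seed = seed)
    searches[[st]] <- forward_search(cohort, phen, st)
  }
  scans[["birthweight"]] <- scan_birth_weight(cohort, fdr = fdr)

  power <- list(
    per_test_alpha = bonferroni_threshold(0.05, nrow(cohort$snp_panel)),
    power_r2_0.023 = power_variance_explained(
      nrow(cohort$subjects), 0.023,
      bonferroni_threshold(0.05, nrow(cohort$snp_panel)), df = 1))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_qc_report(qc, file.path(out_dir, "qc.tsv"))
    for (nm in names(scans)) {
      write_scan(scans[[nm]], file.path(out_dir, paste0("assoc_", nm, ".tsv")))
    }
    for (nm in names(interactions)) {
      if (nrow(interactions[[nm]])) {
        utils::write.table(interactions[[nm]],
                           file.path(out_dir, paste0("interact_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    for (st in names(searches)) {
      utils::write.table(searches[[st]]$trace,
                         file.path(out_dir, paste0("search_", st, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(searches[[st]]$trace)) {
        grDevices::png(file.path(out_dir, paste0("search_", st, ".png")),
                       width = 900, height = 600)
        plot(searches[[st]],
             main = paste("Joint-effect variance trace,", st, "stratum"))
        grDevices::dev.off()
      }
      jsonlite::write_json(
        list(stratum = st, seed = seed, n_perm = n_perm,
             burden = burden_effect(searches[[st]])[c("beta", "se",
                                                      "n_snps")],
             empirical_p = perms[[st]]$p_value,
             min_aic = searches[[st]]$min_aic,
             aic0 = searches[[st]]$aic0),
        file.path(out_dir, paste0("search_", st, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(power, file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(qc = qc, scans = scans, interactions = interactions,
       searches = searches, permutations = perms, power = power,
       seed = seed)
}
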