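#' Minor allele frequency of a dosage vector
#'
#' Dosages count copies of the minor allele (0, 1 or 2); missing entries are
#' excluded.  The returned frequency is
#' (sum of dosages) / (2 x number of non-missing dosages).
#'
#' @param dosages integer-like vector with values in \{0, 1, 2\} or NA.
#' @return allele frequency in [0, 1].
#' @export
minor_allele_frequency <- function(dosages) {
  d <- .check_dosages(dosages)
  sum(d) / (2 * length(d))
}

#' Expected heterozygosity under Hardy-Weinberg equilibrium
#'
#' Returns 2p(1-p), the HWE heterozygote frequency at allele frequency p.
#'
#' @param p allele frequency in [0, 1] (vectorised).
#' @return expected heterozygote frequency, in [0, 0.5].
#' @export
expected_heterozygosity <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("allele frequency must lie in [0, 1]")
  }
  2 * p * (1 - p)
}

#' Observed heterozygosity of a dosage vector
#'
#' Fraction of non-missing genotypes that are heterozygous (dosage 1).
#'
#' @inheritParams minor_allele_frequency
#' @return fraction in [0, 1].
#' @export
observed_heterozygosity <- function(dosages) {
  d <- .check_dosages(dosages)
  mean(d == 1)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test comparing observed genotype counts
#' (n0, n1, n2) to their HWE expectations at the sample allele frequency,
#' without continuity correction — the usual GWAS quality-control test.  For
#' genotype counts the statistic has the closed form
#' \deqn{\chi^2 = n (4 n_0 n_2 - n_1^2)^2 / ((2 n_0 + n_1)^2 (2 n_2 + n_1)^2)}
#'
#' @inheritParams minor_allele_frequency
#' @return list with \code{statistic}, \code{df} (= 1), \code{p_value} and
#'   the genotype \code{counts}.
#' @export
hwe_test <- function(dosages) {
  d <- .check_dosages(dosages)
  if (length(d) < 2L) stop("need at least 2 non-missing genotypes")
  n0 <- sum(d == 0); n1 <- sum(d == 1); n2 <- sum(d == 2)
  n <- n0 + n1 + n2
  if (2 * n0 + n1 == 0L || 2 * n2 + n1 == 0L) {
    stop("HWE test undefined for a monomorphic genotype vector")
  }
  stat <- n * (4 * n0 * n2 - n1^2)^2 / ((2 * n0 + n1)^2 * (2 * n2 + n1)^2)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       counts = c(n0 = n0, n1 = n1, n2 = n2))
}

.check_dosages <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("all genotypes missing: no statistic defined")
  if (!all(d %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  d
}

#' Per-SNP quality-control report
#'
#' Computes call count, sample minor allele frequency, observed and expected
#' heterozygosity and the HWE test p-value for every column of a dosage
#' matrix.  If a sample MAF exceeds 0.5 (a minor/major flip in a finite
#' sample) the statistics are still computed on the stored coding and a
#' warning is issued; no re-polarisation is performed here.
#'
#' @param genotypes numeric matrix, subjects x SNPs, dosages in \{0,1,2\}
#'   or NA, with SNP ids as column names.
#' @return data frame with columns snp_id, n_called, maf, het_obs, het_exp,
#'   hwe_p (NA for monomorphic SNPs).
#' @export
qc_report <- function(genotypes) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)))
  res <- lapply(colnames(genotypes), function(s) {
    g <- genotypes[, s]
    maf <- minor_allele_frequency(g)
    if (maf > 0.5) {
      warning("sample MAF > 0.5 for ", s,
              ": stored minor allele is the sample major allele")
    }
    hwe <- tryCatch(hwe_test(g)$p_value, error = function(e) NA_real_)
    data.frame(snp_id = s, n_called = sum(!is.na(g)), maf = maf,
               het_obs = observed_heterozygosity(g),
               het_exp = expected_heterozygosity(maf),
               hwe_p = hwe, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a quality-control report as TSV
#'
#' @param qc data frame from \code{\link{qc_report}}.
#' @param path output file path.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
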