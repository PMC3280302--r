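#' Candidate SNP panel for BMI association
#'
#' Annotation table for the 23 GWAS-significant BMI candidate SNPs used as
#' the default simulation panel: id, gene label, chromosome, strand,
#' position (bp, NCBI B36), minor/major allele and minor allele frequency.
#'
#' @return data frame with columns snp_id, gene, chr, strand, position,
#'   minor_allele, major_allele, maf.
#' @export
default_snp_panel <- function() {
  panel <- data.frame(
    snp_id = c("rs2568958", "rs2815752", "rs1514175", "rs2867125",
               "rs7561317", "rs13078807", "rs7647305", "rs13107325",
               "rs987237", "rs10968576", "rs925946", "rs6265", "rs10767664",
               "rs10838738", "rs7138803", "rs2241423", "rs6499640",
               "rs1121980", "rs8050136", "rs571312", "rs12970134",
               "rs29941", "rs2287019"),
    gene = c("NEGR1", "NEGR1", "TNNI3K", "TMEM18", "TMEM18", "CADM2",
             "ETV5", "SLC39A8", "TFAP2B", "LRRN6C", "BDNF", "BDNF", "BDNF",
             "MTCH2", "FAIM2", "MAP2K5", "FTO", "FTO", "FTO", "MC4R",
             "MC4R", "KCTD15", "QPCTL"),
    chr = c(1, 1, 1, 2, 2, 3, 3, 4, 6, 9, 11, 11, 11, 11, 12, 15, 16, 16,
            16, 18, 18, 19, 19),
    strand = c("+", "-", "-", "-", "+", "+", "+", "+", "+", "+", "+", "-",
               "+", "+", "+", "+", "+", "-", "+", "-", "+", "-", "+"),
    position = c(72537704, 72585028, 74764232, 612827, 634953, 85966840,
                 187316984, 103407732, 50911009, 28404339, 27623778,
                 27636492, 27682562, 47619625, 48533735, 65873892,
                 52327178, 52366748, 52373776, 55990749, 56035730,
                 39001372, 50894012),
    minor_allele = c("G", "C", "T", "A", "A", "G", "T", "T", "G", "G", "T",
                     "A", "T", "G", "A", "A", "G", "T", "A", "T", "A", "T",
                     "T"),
    major_allele = c("A", "T", "C", "G", "G", "A", "C", "C", "A", "A", "G",
                     "G", "A", "A", "G", "G", "A", "C", "C", "G", "G", "C",
                     "C"),
    maf = c(0.38, 0.38, 0.40, 0.18, 0.19, 0.22, 0.22, 0.09, 0.17, 0.30,
            0.33, 0.19, 0.20, 0.35, 0.37, 0.22, 0.39, 0.42, 0.40, 0.23,
            0.27, 0.31, 0.17),
    stringsAsFactors = FALSE)
  validate_snp_panel(panel)
}

#' Validate a SNP annotation table
#'
#' Checks the panel invariants: required columns present, unique SNP ids,
#' and all minor allele frequencies inside [0, 0.5].
#'
#' @param panel data frame with columns snp_id, gene, chr, strand, position,
#'   minor_allele, major_allele, maf.
#' @return the validated panel (invisibly usable in pipelines).
#' @export
validate_snp_panel <- function(panel) {
  req <- c("snp_id", "gene", "chr", "strand", "position", "minor_allele",
           "major_allele", "maf")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$snp_id)) stop("panel snp_id values must be unique")
  if (any(!is.finite(panel$maf)) || any(panel$maf < 0) || any(panel$maf > 0.5)) {
    stop("panel maf values must lie in [0, 0.5]")
  }
  panel
}

#' Read/write a SNP annotation table (tab-separated)
#'
#' The on-disk layout mirrors the usual candidate-SNP annotation table:
#' header columns snp_id, gene, chr, strand, position, minor_allele,
#' major_allele, maf.
#'
#' @param path file path.
#' @return \code{read_snp_panel}: validated panel data frame.
#' @export
read_snp_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_snp_panel(panel)
}

#' @rdname read_snp_panel
#' @param panel SNP panel data frame.
#' @export
write_snp_panel <- function(panel, path) {
  validate_snp_panel(panel)
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
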