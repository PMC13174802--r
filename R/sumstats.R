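# Reading, quality control and harmonization of GWAS summary statistics
# (the "munge" stage), plus sample-size metadata.

#' Read summary statistics in the munged dialect
#'
#' Tab-delimited with header SNP A1 A2 Z N and optional MAF / INFO columns.
#' A small alias map handles common header variants (snpid, zscore, ...).
#'
#' @param path file path.
#' @return data.frame with canonical column names.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(x) <- toupper(names(x))
  alias <- c(SNPID = "SNP", RSID = "SNP", MARKERNAME = "SNP",
             ZSCORE = "Z", NEFF = "N", FRQ = "MAF", EAF = "MAF")
  hit <- names(x) %in% names(alias)
  names(x)[hit] <- alias[names(x)[hit]]
  need <- c("SNP", "A1", "A2", "Z", "N")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("sumstats file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  x
}

#' Read an LD-score table (CHR SNP BP L2)
#' @param path file path.
#' @return data.frame.
#' @export
read_ld_scores <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("CHR", "SNP", "BP", "L2")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("LD-score file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  x
}

#' Read an allele registry (SNP A1 A2 CHR BP)
#' @param path file path.
#' @return data.frame.
#' @export
read_registry <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "CHR", "BP")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("registry lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(x$SNP)) stopf("registry SNP IDs must be unique")
  x
}

#' Effective sample size of a case-control GWAS
#'
#' The balanced-design equivalent sample size 4 / (1/n_cases +
#' 1/n_controls), used as the regression N for binary traits and as the
#' basis of the liability ascertainment correction.
#'
#' @param n_cases,n_controls positive counts.
#' @return numeric effective N.
#' @examples
#' effective_sample_size(500, 500)     # 1000
#' effective_sample_size(15025, 19763) # ~34142.7
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stopf("case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

.ambiguous <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Quality-control and harmonize summary statistics
#'
#' Restricts to registry SNPs (HapMap3-style allow list), drops
#' strand-ambiguous pairs (A/T, C/G), aligns alleles to the registry
#' (flipping the z sign when the pair is reversed), excludes named genomic
#' regions (the MHC by default elsewhere in the pipeline), and applies
#' strict frequency / imputation-quality filters `maf > maf_min` and
#' `info > info_min`.  Records lacking an optional MAF or INFO column pass
#' the corresponding filter.
#'
#' @param raw data.frame with SNP A1 A2 Z N (optional MAF, INFO).
#' @param registry allele registry (SNP A1 A2 CHR BP).
#' @param maf_min minor-allele-frequency floor (strict), default 0.01.
#' @param info_min imputation-quality floor (strict), default 0.9.
#' @param exclude_regions list of `list(chr=, start=, end=)`, 1-based
#'   inclusive.
#' @return list with `sumstats` (harmonized table) and `report` (drop
#'   counts per rule; counts plus retained always equal the input count).
#' @export
munge <- function(raw, registry, maf_min = 0.01, info_min = 0.9,
                  exclude_regions = list(mhc_region())) {
  if (maf_min < 0 || maf_min > 1 || info_min < 0 || info_min > 1)
    stopf("maf_min and info_min must lie in [0,1]")
  n_in <- nrow(raw)
  rep0 <- c(not_in_registry = 0L, region = 0L, ambiguous = 0L,
            allele_mismatch = 0L, MAF = 0L, INFO = 0L)

  ri <- match(raw$SNP, registry$SNP)
  keep <- !is.na(ri)
  rep0["not_in_registry"] <- sum(!keep)
  x <- raw[keep, , drop = FALSE]
  reg <- registry[ri[keep], , drop = FALSE]

  # region exclusion uses registry coordinates
  in_region <- rep(FALSE, nrow(x))
  for (rg in exclude_regions) {
    in_region <- in_region |
      (reg$CHR == rg$chr & reg$BP >= rg$start & reg$BP <= rg$end)
  }
  rep0["region"] <- sum(in_region)
  x <- x[!in_region, , drop = FALSE]
  reg <- reg[!in_region, , drop = FALSE]

  amb <- .ambiguous(x$A1, x$A2)
  rep0["ambiguous"] <- sum(amb)
  x <- x[!amb, , drop = FALSE]
  reg <- reg[!amb, , drop = FALSE]

  direct <- x$A1 == reg$A1 & x$A2 == reg$A2
  flipped <- x$A1 == reg$A2 & x$A2 == reg$A1
  mism <- !(direct | flipped)
  rep0["allele_mismatch"] <- sum(mism)
  x <- x[!mism, , drop = FALSE]
  flipped <- flipped[!mism]
  reg <- reg[!mism, , drop = FALSE]
  x$Z[flipped] <- -x$Z[flipped]
  x$A1 <- reg$A1
  x$A2 <- reg$A2

  if ("MAF" %in% names(x)) {
    bad <- !is.na(x$MAF) & !(x$MAF > maf_min)
    rep0["MAF"] <- sum(bad)
    x <- x[!bad, , drop = FALSE]
  }
  if ("INFO" %in% names(x)) {
    bad <- !is.na(x$INFO) & !(x$INFO > info_min)
    rep0["INFO"] <- sum(bad)
    x <- x[!bad, , drop = FALSE]
  }

  report <- list(input = n_in, dropped = rep0, retained = nrow(x))
  if (nrow(x) == 0L)
    stopf("munge retained zero records; downstream analysis would be meaningless")
  rownames(x) <- NULL
  list(sumstats = x, report = report)
}

#' Default MHC exclusion interval
#'
#' chr6:26,000,000-34,000,000 (1-based inclusive), a conventional span for
#' the extended MHC whose long-range LD distorts LD-score regression.
#' @return list(chr, start, end).
#' @export
mhc_region <- function() list(chr = 6, start = 26e6, end = 34e6)
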