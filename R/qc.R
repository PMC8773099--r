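#' Per-SNP quality control: minor allele frequency and missingness
#'
#' Applies the two array-QC exclusion rules used ahead of association
#' analysis: SNPs with a minor allele frequency of 0 (monomorphic over all
#' non-missing calls, both arms pooled) are removed first, then SNPs whose
#' missing rate is strictly greater than `missing_threshold`. Retained SNP
#' order is preserved. A SNP with no non-missing calls at all is removed
#' under the missingness rule with a warning.
#'
#' @param x A [snp_matrix()] (or bare subjects x SNPs matrix).
#' @param missing_threshold Maximum tolerated per-SNP missing rate
#'   (strict inequality; default 0.10).
#' @return A list of class `qc_result`: `genotypes` (filtered
#'   [snp_matrix()]), `summary` (one-row tibble with `n_input`,
#'   `n_removed_maf0`, `n_removed_missing`, `n_retained`) and `per_snp`
#'   (tibble: `snp_id`, `maf`, `missing_rate`, `status`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_cases = 15, n_controls = 15,
#'                                       n_snps = 40, seed = 2))
#' qc <- filter_snps(cohort$genotypes)
#' glance(qc)
filter_snps <- function(x, missing_threshold = 0.10) {
  x <- as_snp_matrix(x)
  calls <- x$calls
  if (ncol(calls) == 0 || nrow(calls) == 0) abort("empty genotype matrix.")
  n_obs <- colSums(!is.na(calls))
  miss_rate <- 1 - n_obs / nrow(calls)
  alt_freq <- colSums(calls, na.rm = TRUE) / (2 * n_obs)  # NaN when all missing
  maf <- pmin(alt_freq, 1 - alt_freq)

  all_missing <- n_obs == 0
  if (any(all_missing)) {
    warn(sprintf("%d SNP(s) with all calls missing removed under the missingness rule: %s",
                 sum(all_missing),
                 paste(head(colnames(calls)[all_missing], 5), collapse = ", ")))
  }
  rm_maf0 <- !all_missing & !is.nan(maf) & maf == 0
  rm_miss <- !rm_maf0 & (miss_rate > missing_threshold)
  status <- dplyr::case_when(
    rm_maf0 ~ "removed_maf0",
    rm_miss ~ "removed_missing",
    TRUE    ~ "retained"
  )

  per_snp <- tibble(
    snp_id = colnames(calls),
    maf = ifelse(is.nan(maf), NA_real_, maf),
    missing_rate = miss_rate,
    status = status
  )
  keep <- status == "retained"
  summary <- tibble(
    n_input = ncol(calls),
    n_removed_maf0 = sum(rm_maf0),
    n_removed_missing = sum(rm_miss),
    n_retained = sum(keep)
  )
  structure(
    list(genotypes = x[, keep], summary = summary, per_snp = per_snp,
         missing_threshold = missing_threshold),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<qc_result> %d SNPs in: %d removed (MAF 0), %d removed (missing > %g), %d retained\n",
              s$n_input, s$n_removed_maf0, s$n_removed_missing,
              x$missing_threshold, s$n_retained))
  invisible(x)
}

#' @export
tidy.qc_result <- function(x, ...) x$per_snp

#' @export
glance.qc_result <- function(x, ...) x$summary

#' Label clopidogrel resistance from PRU
#'
#' High on-treatment platelet reactivity defines resistance: a patient with
#' PRU strictly greater than `threshold` (default 234) is labelled
#' resistant. Controls (non-cases) are left unlabelled (`NA`) because they
#' are not on clopidogrel. Every case subject must have a PRU value.
#'
#' @param pheno Phenotype tibble with `subject_id`, `case`, `pru`.
#' @param threshold PRU cut-off (strict inequality).
#' @return `pheno` with its `resistance` column (re)computed.
#' @export
label_resistance <- function(pheno, threshold = 234) {
  miss <- pheno$case & is.na(pheno$pru)
  if (any(miss)) {
    abort(sprintf("case subject(s) missing PRU: %s",
                  paste(head(pheno$subject_id[miss], 10), collapse = ", ")))
  }
  pheno$resistance <- ifelse(pheno$case, pheno$pru > threshold, NA)
  pheno
}
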