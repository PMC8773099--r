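#' Allelic 2x2 contingency table for one SNP
#'
#' Counts alternate and reference alleles per label arm under additive
#' coding: the alternate count of an arm is the sum of its non-missing
#' calls, the reference count is `2 * n_nonmissing - alt`. Missing calls
#' are excluded pairwise. An arm with no non-missing calls makes the table
#' untestable.
#'
#' @param calls Integer vector of additive genotype calls (0/1/2/NA).
#' @param labels Logical vector, `TRUE` for the first arm (e.g. resistant
#'   or case); must contain no `NA`.
#' @return A 2x2 integer matrix, rows = arms (`TRUE` first), columns =
#'   `alt`, `ref`, with attribute `untestable`.
#' @export
#' @examples
#' allele_table(c(2, 2, 1, 0, 0, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
allele_table <- function(calls, labels) {
  if (anyNA(labels)) abort("`labels` must not contain NA.")
  labels <- as.logical(labels)
  ok <- !is.na(calls)
  n1 <- sum(ok & labels); n0 <- sum(ok & !labels)
  alt1 <- sum(calls[ok & labels]); alt0 <- sum(calls[ok & !labels])
  tab <- matrix(as.integer(c(alt1, 2 * n1 - alt1, alt0, 2 * n0 - alt0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("TRUE", "FALSE"),
                                allele = c("alt", "ref")))
  attr(tab, "untestable") <- (n1 == 0 || n0 == 0)
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' The uncorrected (no continuity correction) Pearson statistic in closed
#' form, `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the p-value from
#' the upper tail of the 1-df chi-square distribution. A zero row or column
#' margin makes the table untestable (`NA` statistic and p, no exception).
#'
#' @param tab 2x2 numeric matrix of non-negative counts.
#' @return One-row tibble: `chi2`, `p_value`, `untestable`.
#' @export
#' @examples
#' chi2_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
chi2_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("`tab` must be 2x2.")
  if (any(tab < 0)) abort("counts must be non-negative.")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(tibble(chi2 = NA_real_, p_value = NA_real_, untestable = TRUE))
  }
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  tibble(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
         untestable = FALSE)
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' `OR = ad / (bc)`; when any cell is zero, `correction` (default 0.5) is
#' first added to all four cells so the estimate is always finite.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param correction Zero-cell pseudo-count.
#' @return The odds ratio (positive real).
#' @export
#' @examples
#' odds_ratio_2x2(matrix(c(5, 0, 5, 5), 2, byrow = TRUE))  # 11 with 0.5
odds_ratio_2x2 <- function(tab, correction = 0.5) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("`tab` must be 2x2.")
  if (any(tab == 0)) tab <- tab + correction
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Derive binary association labels from a phenotype table
#'
#' `contrast = "resistance"` contrasts resistant vs non-resistant patients
#' (controls and unlabelled subjects are dropped); `"case_control"`
#' contrasts patients vs the healthy controls (group IV).
#'
#' @param pheno Phenotype tibble.
#' @param contrast `"resistance"` or `"case_control"`.
#' @return Named logical vector (names = subject ids), NA-free.
#' @export
association_labels <- function(pheno, contrast = c("resistance", "case_control")) {
  contrast <- match.arg(contrast)
  lab <- if (contrast == "resistance") {
    as.logical(pheno$resistance)
  } else {
    as.logical(pheno$case)
  }
  names(lab) <- pheno$subject_id
  lab[!is.na(lab)]
}

#' Per-SNP allelic chi-square association scan
#'
#' Stage 1 of the signature discovery pipeline: for every SNP, builds the
#' allelic 2x2 table ([allele_table()]), computes the uncorrected Pearson
#' chi-square ([chi2_test()]) and odds ratio ([odds_ratio_2x2()]), and flags
#' SNPs passing the joint filter `p < alpha` and `OR > or_threshold` (both
#' strict). No multiple-testing correction is applied — the filter operates
#' on raw p-values by design; see the package vignette.
#'
#' @param x A [snp_matrix()] or matrix.
#' @param pheno Phenotype tibble, or a named logical label vector.
#' @param contrast Label contrast when `pheno` is a table; see
#'   [association_labels()]. Default `"resistance"`.
#' @param alpha Significance threshold (strict).
#' @param or_threshold Odds-ratio threshold (strict). The published filter
#'   uses 10; the companion methods text mentions > 1, available by setting
#'   `or_threshold = 1`.
#' @param correction Haldane-Anscombe pseudo-count for zero cells.
#' @return A tibble with one row per SNP: allele counts (`alt_1`, `ref_1`
#'   for the `TRUE` arm; `alt_0`, `ref_0`), `chi2`, `p_value`, `odds_ratio`,
#'   `untestable`, `pass`.
#' @export
snp_association <- function(x, pheno, contrast = c("resistance", "case_control"),
                            alpha = 0.05, or_threshold = 10, correction = 0.5) {
  x <- as_snp_matrix(x)
  if (is.data.frame(pheno)) {
    lab <- association_labels(pheno, match.arg(contrast))
  } else {
    lab <- pheno[!is.na(pheno)]
  }
  common <- intersect(rownames(x$calls), names(lab))
  if (length(common) < 2) abort("fewer than two labelled subjects overlap the genotype matrix.")
  calls <- x$calls[common, , drop = FALSE]
  lab <- as.logical(lab[common])

  obs <- !is.na(calls)
  calls0 <- calls; calls0[!obs] <- 0L
  n1 <- colSums(obs[lab, , drop = FALSE]); n0 <- colSums(obs[!lab, , drop = FALSE])
  a <- colSums(calls0[lab, , drop = FALSE])        # alt alleles, TRUE arm
  c_ <- colSums(calls0[!lab, , drop = FALSE])      # alt alleles, FALSE arm
  b <- 2 * n1 - a; d <- 2 * n0 - c_
  n <- a + b + c_ + d

  m1 <- a + b; m2 <- c_ + d; m3 <- a + c_; m4 <- b + d
  untestable <- (m1 == 0) | (m2 == 0) | (m3 == 0) | (m4 == 0)
  chi2 <- ifelse(untestable, NA_real_,
                 n * (a * d - b * c_)^2 / (m1 * m2 * m3 * m4))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)

  zero <- (a == 0) | (b == 0) | (c_ == 0) | (d == 0)
  ac <- a + correction * zero; bc <- b + correction * zero
  cc <- c_ + correction * zero; dc <- d + correction * zero
  or <- ifelse(untestable, NA_real_, (ac * dc) / (bc * cc))

  tibble(
    snp_id = colnames(calls),
    alt_1 = as.integer(unname(a)), ref_1 = as.integer(unname(b)),
    alt_0 = as.integer(unname(c_)), ref_0 = as.integer(unname(d)),
    chi2 = unname(chi2), p_value = unname(p), odds_ratio = unname(or),
    untestable = unname(untestable),
    pass = unname(!untestable & !is.na(p) & p < alpha & or > or_threshold)
  )
}

#' Keep associations passing the significance and odds-ratio filter
#'
#' Strict inequalities on both thresholds; untestable records are never
#' retained.
#'
#' @param assoc Tibble from [snp_association()].
#' @param alpha Significance threshold.
#' @param or_threshold Odds-ratio threshold.
#' @return The retained rows, `pass` recomputed.
#' @export
filter_associations <- function(assoc, alpha = 0.05, or_threshold = 10) {
  assoc %>%
    mutate(pass = !.data$untestable & !is.na(.data$p_value) &
             .data$p_value < alpha & .data$odds_ratio > or_threshold) %>%
    filter(.data$pass)
}
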