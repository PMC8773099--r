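# random genotype matrix with complete SNP metadata (VCF-writable)
rand_snp_matrix <- function(n_sub = 8, n_snp = 6, missing_rate = 0.1, seed = 1) {
  withr::with_seed(seed, {
    calls <- matrix(sample(0:2, n_sub * n_snp, replace = TRUE),
                    n_sub, n_snp,
                    dimnames = list(sprintf("s%03d", seq_len(n_sub)),
                                    sprintf("rs%04d", seq_len(n_snp))))
    calls[matrix(runif(n_sub * n_snp) < missing_rate, n_sub)] <- NA_integer_
    meta <- tibble::tibble(
      snp_id = colnames(calls),
      chrom = as.character(sample(1:22, n_snp, replace = TRUE)),
      pos = sort(sample.int(1e6, n_snp)),
      ref = sample(c("A", "C", "G", "T"), n_snp, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_snp, replace = TRUE),
      gene = ifelse(runif(n_snp) < 0.5, sprintf("GENE%02d", seq_len(n_snp)),
                    NA_character_)
    )
    snp_matrix(calls, meta)
  })
}

# genotype matrix with one perfectly separating SNP among noise
separable_fixture <- function(n_per_class = 30, n_noise = 20, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(c(TRUE, FALSE), each = n_per_class)
    n <- length(y)
    sep <- ifelse(y, 2L, 0L)
    noise <- matrix(sample(0:2, n * n_noise, replace = TRUE), n, n_noise)
    calls <- cbind(sep, noise)
    colnames(calls) <- c("snp_sep", sprintf("snp_n%02d", seq_len(n_noise)))
    rownames(calls) <- sprintf("s%03d", seq_len(n))
    list(genotypes = snp_matrix(calls), labels = y)
  })
}

# trapezoidal ROC integration, independent of the rank-statistic AUC
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
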