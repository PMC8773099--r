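test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE,
                       prob = c(0.4, 0.6))
      if (length(unique(labels)) < 2) next
      scores <- sample(round(rnorm(n), 2))  # rounded -> ties occur
      expect_equal(auc_rank(scores, labels), auc_trapezoid(scores, labels),
                   tolerance = 1e-9)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    labels <- sample(c(TRUE, FALSE), 80, replace = TRUE)
    scores <- rnorm(80) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("a separable SNP yields perfect AUC and accuracy at every k", {
  fx <- separable_fixture(n_per_class = 25, n_noise = 6, seed = 5)
  ranked <- c("snp_sep", sprintf("snp_n%02d", 1:6))
  cv <- evaluate_curve(fx$genotypes, fx$labels, ranked,
                       max_features = 3, n_iterations = 5, seed = 1)
  expect_true(all(cv$curve$auc == 1))
  expect_true(all(cv$curve$accuracy == 1))
  expect_equal(cv$selection$n_features, 1)
  expect_identical(cv$selection$snp_ids, "snp_sep")
})

test_that("null genotypes give chance-level AUC", {
  aucs <- vapply(1:8, function(s) {
    withr::with_seed(s, {
      n <- 400
      calls <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4,
                      dimnames = list(sprintf("s%03d", 1:n),
                                      sprintf("snp%02d", 1:4)))
      y <- rep(c(TRUE, FALSE), each = n / 2)
    })
    cv <- evaluate_curve(snp_matrix(calls), y, colnames(calls),
                         models = "svm", max_features = 2,
                         n_iterations = 5, seed = s)
    mean(cv$curve$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("signature selection picks the minimal sufficient feature count", {
  flat <- tidyr::expand_grid(model = c("svm", "forest"), n_features = 1:6) |>
    dplyr::mutate(auc = 0.9, accuracy = 0.8)
  expect_equal(select_signature(flat)$n_features, 1)

  mono <- tibble::tibble(model = "svm", n_features = 1:6,
                         auc = seq(0.5, 0.95, length.out = 6), accuracy = 0.8)
  expect_equal(select_signature(mono)$n_features, 6)

  plateau <- tibble::tibble(model = "svm", n_features = 1:6,
                            auc = c(0.7, 0.85, 0.93, 0.931, 0.929, 0.932),
                            accuracy = 0.9)
  expect_equal(select_signature(plateau)$n_features, 3)

  # model ties at the selected k break by name order
  tie <- tibble::tibble(model = c("svm", "forest"), n_features = 1,
                        auc = 0.9, accuracy = 0.8)
  expect_equal(select_signature(tie)$model, "forest")
})

test_that("requesting more features than ranked SNPs errors", {
  fx <- separable_fixture(n_per_class = 10, n_noise = 3, seed = 5)
  expect_error(evaluate_curve(fx$genotypes, fx$labels, c("snp_sep", "snp_n01"),
                              max_features = 5, n_iterations = 3),
               "exceeds")
})

test_that("the annotation filter restricts the sweep to annotated SNPs", {
  fx <- separable_fixture(n_per_class = 20, n_noise = 4, seed = 6)
  ann <- tibble::tibble(snp_id = c("snp_sep", "snp_n01"),
                        gene = c("GENEA", NA))
  cv <- evaluate_curve(fx$genotypes, fx$labels,
                       c("snp_n01", "snp_sep", "snp_n02"),
                       models = "tree", max_features = 1,
                       n_iterations = 3, annotation = ann)
  expect_identical(cv$snp_order, "snp_sep")
})

test_that("genotype-frequency test drops empty columns and reduces df", {
  same <- genotype_frequency_test(rep(c(0, 1, 2), 10),
                                  rep(c(TRUE, FALSE), 15))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  split2 <- genotype_frequency_test(c(rep(0, 20), rep(2, 20)),
                                    c(rep(TRUE, 20), rep(FALSE, 20)))
  expect_equal(split2$chi2, 40)
  expect_equal(split2$df, 1)        # middle genotype column dropped
  expect_lt(split2$p_value, 0.005)

  mono <- genotype_frequency_test(rep(0, 20), rep(c(TRUE, FALSE), 10))
  expect_true(mono$untestable)
})

test_that("genotype-frequency chi-square matches stats::chisq.test", {
  withr::with_seed(15, {
    calls <- sample(0:2, 120, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    labels <- rep(c(TRUE, FALSE), each = 60)
  })
  mine <- genotype_frequency_test(calls, labels)
  ref <- suppressWarnings(chisq.test(table(labels, calls), correct = FALSE))
  expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  batch <- test_genotype_frequencies(
    snp_matrix(matrix(calls, 120, 1, dimnames = list(sprintf("s%03d", 1:120), "snpX"))),
    setNames(labels, sprintf("s%03d", 1:120)))
  expect_equal(batch$chi2, mine$chi2)
})
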