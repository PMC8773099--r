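test_that("allele tables count alternate alleles with pairwise deletion", {
  tab <- allele_table(c(2, 2, 1, 0, 0, 1),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(tab), matrix(c(5L, 1L, 1L, 5L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_false(attr(tab, "untestable"))

  # missing calls excluded pairwise
  tab2 <- allele_table(c(2, NA, 1, 0, NA, 1),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(tab2), matrix(c(3L, 1L, 1L, 3L), 2, byrow = TRUE),
               ignore_attr = TRUE)

  # an arm with no non-missing calls is untestable
  tab3 <- allele_table(c(NA, NA, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(attr(tab3, "untestable"))

  # all-heterozygous arms give identical rows
  tab4 <- allele_table(rep(1, 8), rep(c(TRUE, FALSE), each = 4))
  expect_equal(tab4[1, ], tab4[2, ])
})

test_that("Pearson chi-square matches its closed form and null case", {
  r0 <- chi2_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)

  r <- chi2_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(r$chi2, 20)                       # 80 * 800^2 / 40^4
  expect_equal(r$p_value, 7.744216e-06, tolerance = 1e-6)

  # zero margin -> untestable flag, no exception
  r2 <- chi2_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_true(r2$untestable)
  expect_true(is.na(r2$chi2))
})

test_that("chi-square agrees with the expected-count Pearson oracle", {
  withr::with_seed(13, {
    for (i in 1:300) {
      tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1, 2)
      mine <- chi2_test(tab)
      oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(mine$chi2, unname(oracle$statistic), tolerance = 1e-12)
      expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
    }
  })
})

test_that("odds ratios use the Haldane-Anscombe zero-cell correction", {
  expect_equal(odds_ratio_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE)), 9)
  expect_equal(odds_ratio_2x2(matrix(c(5, 0, 5, 5), 2, byrow = TRUE)), 11)
  expect_equal(odds_ratio_2x2(matrix(c(7, 7, 7, 7), 2)), 1)
  expect_true(is.finite(odds_ratio_2x2(matrix(c(5, 0, 0, 5), 2))))
})

test_that("swapping both row and column labels fixes chi2, inverts OR", {
  withr::with_seed(17, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 10) + 1, 2)
      swapped <- tab[2:1, 2:1]
      expect_equal(chi2_test(tab)$chi2, chi2_test(swapped)$chi2)
      expect_equal(chi2_test(tab)$p_value, chi2_test(swapped)$p_value)
      expect_equal(odds_ratio_2x2(tab), odds_ratio_2x2(swapped))
      flipped <- tab[2:1, ]
      expect_equal(odds_ratio_2x2(flipped), 1 / odds_ratio_2x2(tab))
    }
  })
})

test_that("the association filter applies strict thresholds", {
  rec <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    p_value = c(0.04, 0.04, 0.05, 0.04),
    odds_ratio = c(12, 5, 12, 10),
    untestable = FALSE, pass = NA
  )
  kept <- filter_associations(rec)
  expect_identical(kept$snp_id, "a")  # p = 0.05 and OR = 10 both excluded

  rec$untestable[1] <- TRUE
  expect_equal(nrow(filter_associations(rec)), 0)
})

test_that("the vectorised scan matches per-SNP scalar computation", {
  co <- simulate_cohort(cohort_spec(n_cases = 25, n_controls = 25,
                                    n_snps = 30, missing_rate = 0.1,
                                    seed = 19))
  assoc <- snp_association(co$genotypes, co$phenotypes,
                           contrast = "case_control")
  lab <- co$phenotypes$case
  for (j in sample(30, 8)) {
    tab <- allele_table(co$genotypes$calls[, j], lab)
    sc <- chi2_test(tab)
    expect_equal(assoc$chi2[j], sc$chi2)
    expect_equal(assoc$p_value[j], sc$p_value)
    expect_equal(assoc$odds_ratio[j], odds_ratio_2x2(tab))
  }
})

test_that("both label contrasts are available", {
  co <- simulate_cohort(cohort_spec(n_cases = 40, n_controls = 40,
                                    n_snps = 20, seed = 23))
  lab_cc <- association_labels(co$phenotypes, "case_control")
  expect_length(lab_cc, 80)
  lab_res <- association_labels(co$phenotypes, "resistance")
  expect_true(all(names(lab_res) %in%
                    co$phenotypes$subject_id[co$phenotypes$case]))
  expect_false(anyNA(lab_res))
})
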