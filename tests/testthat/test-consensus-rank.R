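test_that("splits are stratified 80/20, disjoint, and seed-reproducible", {
  labels <- rep(c(TRUE, FALSE), each = 50)
  sp <- bootstrap_splits(labels, n_iterations = 25, seed = 3)
  for (s in sp) {
    expect_length(s$train, 80)
    expect_length(s$validation, 20)
    expect_length(intersect(s$train, s$validation), 0)
    # stratification: class proportions preserved within one subject
    expect_equal(sum(labels[s$train]), 40)
  }
  sp2 <- bootstrap_splits(labels, n_iterations = 25, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, bootstrap_splits(labels, n_iterations = 25,
                                              seed = 4)))
})

test_that("uneven classes keep train quota within one subject of fraction", {
  labels <- c(rep(TRUE, 33), rep(FALSE, 67))
  sp <- bootstrap_splits(labels, n_iterations = 10, seed = 1)
  for (s in sp) {
    expect_equal(length(s$train), 80)
    expect_lte(abs(sum(labels[s$train]) - 0.8 * 33), 1)
  }
})

test_that("degenerate label classes are rejected", {
  expect_error(bootstrap_splits(c(TRUE, rep(FALSE, 20)), 5), "at least 2")
  expect_error(bootstrap_splits(rep(TRUE, 4), 5), "at least 10|at least 2")
})

test_that("with-replacement mode bootstraps the training set", {
  labels <- rep(c(TRUE, FALSE), each = 20)
  sp <- bootstrap_splits(labels, n_iterations = 20, replace = TRUE, seed = 2)
  any_dup <- any(vapply(sp, function(s) anyDuplicated(s$train) > 0, logical(1)))
  expect_true(any_dup)
  for (s in sp) {
    expect_length(intersect(s$train, s$validation), 0)
  }
})

test_that("a perfectly separating SNP is ranked first by all three learners", {
  fx <- separable_fixture(n_per_class = 30, n_noise = 20, seed = 5)
  for (m in c("forest", "svm", "lasso")) {
    ord <- rank_snps_once(fx$genotypes$calls, fx$labels, method = m, seed = 1)
    expect_equal(ord[1], "snp_sep")
  }
})

test_that("identical features tie and break by SNP id", {
  withr::with_seed(8, {
    v <- sample(0:2, 30, replace = TRUE)
    calls <- cbind(bbb = v, aaa = v, ccc = v)
    rownames(calls) <- sprintf("s%02d", 1:30)
    y <- rep(c(TRUE, FALSE), 15)
  })
  ord <- rank_snps_once(calls, y, method = "svm", seed = 1)
  expect_identical(ord, c("aaa", "bbb", "ccc"))
})

test_that("aggregate_counts counts memberships with deterministic ties", {
  top <- tidyr::expand_grid(iteration = 1:100,
                            method = c("forest", "svm", "lasso")) |>
    dplyr::mutate(snp_id = "always")
  top <- dplyr::bind_rows(top,
                          tibble::tibble(iteration = 1, method = "svm",
                                         snp_id = "zonce"),
                          tibble::tibble(iteration = 2, method = "svm",
                                         snp_id = "aonce"))
  counts <- aggregate_counts(top, c("always", "zonce", "aonce", "never"))
  expect_equal(counts$count[counts$snp_id == "always"], 300)
  expect_equal(counts$count[counts$snp_id == "never"], 0)
  # equal counts order by ascending SNP id
  expect_identical(counts$snp_id, c("always", "aonce", "zonce", "never"))
  expect_identical(counts$rank, 1:4)
})

test_that("consensus ranking is deterministic and conserves counts", {
  co <- simulate_cohort(cohort_spec(n_cases = 25, n_controls = 25,
                                    n_snps = 15, n_causal = 1,
                                    causal_or = 12, missing_rate = 0.05,
                                    seed = 31))
  lab <- association_labels(co$phenotypes, "case_control")
  r1 <- consensus_rank(co$genotypes, lab, n_iterations = 10, top_k = 5,
                       seed = 41)
  r2 <- consensus_rank(co$genotypes, lab, n_iterations = 10, top_k = 5,
                       seed = 41)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$top_sets, r2$top_sets)
  expect_equal(sum(r1$counts$count), 10 * 3 * 5)
  expect_true(all(r1$counts$count <= 30))
  expect_equal(r1$counts$rank, seq_len(nrow(r1$counts)))
})

test_that("a strong planted SNP dominates the consensus counts", {
  co <- simulate_cohort(cohort_spec(n_cases = 60, n_controls = 60,
                                    n_snps = 30, n_causal = 1,
                                    causal_or = 15, seed = 37))
  lab <- association_labels(co$phenotypes, "case_control")
  r <- consensus_rank(co$genotypes, lab, n_iterations = 15, top_k = 5,
                      seed = 43)
  expect_equal(r$counts$snp_id[1], co$causal_snps)
})
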