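test_that("snp_matrix validates ids and call values", {
  calls <- matrix(0L, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(snp_matrix(calls), "duplicate subject")
  calls <- matrix(c(0L, 3L, 1L, 2L), 2, 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(snp_matrix(calls), "0, 1 or 2")
  calls <- matrix(0:1, 2, 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(snp_matrix(calls), "duplicate SNP")
})

test_that("VCF genotype coding maps to additive calls, phased accepted", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1|1", "./."), collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes(path)
  expect_equal(unname(g$calls[, "rs1"]), c(0L, 1L, 2L, NA))
  expect_equal(g$snp_meta$chrom, "1")
  expect_equal(g$snp_meta$pos, 100L)
})

test_that("multi-allelic VCF records are rejected with the SNP named", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "100", "rs_bad", "A", "G,T", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(read_genotypes(path), "rs_bad")
})

test_that("write/read round-trips are the identity for both formats", {
  for (i in 1:100) {
    g <- rand_snp_matrix(n_sub = sample(2:10, 1), n_snp = sample(1:8, 1),
                         missing_rate = 0.15, seed = i)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(g, tsv)
    g2 <- read_genotypes(tsv)
    expect_identical(g2$calls, g$calls)
  }
  # VCF additionally round-trips the SNP metadata (incl. GENE INFO tag)
  g <- rand_snp_matrix(n_sub = 6, n_snp = 5, seed = 99)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, vcf)
  g2 <- read_genotypes(vcf)
  expect_identical(g2$calls, g$calls)
  expect_equal(g2$snp_meta, g$snp_meta)
})

test_that("missing calls are written as ./. in VCF and NA in TSV", {
  calls <- matrix(c(1L, NA), 1, 2,
                  dimnames = list("s1", c("rs1", "rs2")))
  meta <- tibble::tibble(snp_id = c("rs1", "rs2"), chrom = "1", pos = 1:2,
                         ref = "A", alt = "G", gene = NA_character_)
  g <- snp_matrix(calls, meta)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, vcf)
  body <- readLines(vcf)
  expect_match(body[length(body)], "\\./\\.")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, tsv)
  expect_match(readLines(tsv)[2], "NA")
})

test_that("an empty matrix writes a header-only TSV", {
  calls <- matrix(integer(0), 0, 0, dimnames = list(character(0), NULL))
  colnames(calls) <- character(0)
  rownames(calls) <- character(0)
  g <- structure(list(calls = calls,
                      snp_meta = tibble::tibble(snp_id = character(0),
                                                chrom = character(0),
                                                pos = integer(0),
                                                ref = character(0),
                                                alt = character(0),
                                                gene = character(0))),
                 class = "snp_matrix")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, tsv)
  expect_identical(readLines(tsv), "subject_id")
})

test_that("phenotype reading validates labels, PRU and resistance rule", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    subject_id = c("p1", "p2", "c1"), group = c("I", "II", "IV"),
    case = c(TRUE, TRUE, FALSE), pru = c(250, 234, NA)
  ), path)
  ph <- label_resistance(read_phenotypes(path))
  expect_true(ph$resistance[ph$subject_id == "p1"])
  expect_false(ph$resistance[ph$subject_id == "p2"])  # strict >234
  expect_true(is.na(ph$resistance[ph$subject_id == "c1"]))

  readr::write_tsv(tibble::tibble(subject_id = "x", group = "V",
                                  case = TRUE, pru = 10), path)
  expect_error(read_phenotypes(path), "unknown group")
  readr::write_tsv(tibble::tibble(subject_id = "x", group = "I",
                                  case = TRUE, pru = -5), path)
  expect_error(read_phenotypes(path), "negative PRU")
})

test_that("edge lists drop self-loops with a message", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(symbol_a = c("A", "B"),
                                  symbol_b = c("A", "C")), path)
  expect_message(el <- read_edge_list(path), "1 self-loop")
  expect_equal(nrow(el), 1)
  expect_equal(el$symbol_a, "B")
})
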