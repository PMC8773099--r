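#' Read a genotype matrix from TSV or minimal VCF
#'
#' The TSV dialect is a "feature table": one row per subject, first column
#' `subject_id`, remaining columns one SNP each with additive-coded calls
#' (0/1/2, `NA` for missing). The VCF dialect is v4.2 with a single `GT`
#' FORMAT field; `0/0`, `0/1`, `1/1` and `./.` map to calls 0, 1, 2 and
#' missing, phased separators (`|`) are accepted, and multi-allelic records
#' are rejected (the analysis is biallelic throughout).
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A [snp_matrix()]. For VCF input the SNP metadata (chromosome,
#'   position, ref/alt alleles, and any `GENE=` INFO tag) is populated; TSV
#'   carries calls only.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_integer()
  ), na = c("NA", ""))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed genotype TSV at line %d: expected %s, got %s.",
                  probs$row[1] + 1L, probs$expected[1], probs$actual[1]))
  }
  if (!"subject_id" %in% names(df)) abort("genotype TSV must have a `subject_id` column.")
  calls <- as.matrix(df[setdiff(names(df), "subject_id")])
  rownames(calls) <- df$subject_id
  snp_matrix(calls)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    abort(sprintf("multi-allelic record(s) not supported: %s",
                  paste(head(fix$ID[multi], 5), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), fix$ID))
  known <- !is.na(gt) & gt != "./." & gt != "."
  bad <- known & !(gt %in% names(code))
  if (any(bad)) {
    abort(sprintf("unrecognised GT value '%s' at SNP %s.",
                  gt[which(bad)[1]], fix$ID[which(bad, arr.ind = TRUE)[1, 1]]))
  }
  calls[t(known)] <- code[t(gt)[t(known)]]
  gene <- ifelse(grepl("GENE=", fix$INFO),
                 sub(".*GENE=([^;]+).*", "\\1", fix$INFO), NA_character_)
  meta <- tibble(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene = gene
  )
  snp_matrix(calls, meta)
}

#' Write a genotype matrix to TSV or minimal VCF
#'
#' Round-trips with [read_genotypes()]: TSV keeps subject ids and calls,
#' VCF additionally keeps the SNP metadata (a `GENE=` INFO tag records the
#' gene symbol). Missing calls are written as `NA` (TSV) or `./.` (VCF).
#'
#' @param x A [snp_matrix()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("auto", "tsv", "vcf")) {
  x <- as_snp_matrix(x)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- tibble(subject_id = rownames(x$calls) %||% character(0))
    if (ncol(x$calls) > 0) {
      df <- dplyr::bind_cols(df, as_tibble(as.data.frame(x$calls)))
    }
    readr::write_tsv(df, path, na = "NA")
  } else {
    meta <- x$snp_meta
    if (anyNA(meta$chrom) || anyNA(meta$pos) || anyNA(meta$ref) || anyNA(meta$alt)) {
      abort("VCF output needs complete snp_meta (chrom, pos, ref, alt).")
    }
    gt_char <- c("0/0", "0/1", "1/1")[x$calls + 1L]
    gt_char[is.na(gt_char)] <- "./."
    gt <- matrix(gt_char, nrow = nrow(x$calls))
    info <- ifelse(is.na(meta$gene) | meta$gene == "", ".",
                   paste0("GENE=", meta$gene))
    body <- paste(meta$chrom, meta$pos, meta$snp_id, meta$ref, meta$alt,
                  ".", "PASS", info, "GT",
                  apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", rownames(x$calls)), collapse = "\t"),
      body
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a TSV with columns `subject_id`, `group` (one of I, II, III, IV;
#' IV are the healthy controls), `case` (logical/0-1), `pru` (P2Y12 reaction
#' units, may be missing), plus any further covariate columns, which are
#' kept as-is. A `resistance` column, when present, is validated against the
#' PRU > 234 rule; otherwise it is added as `NA` (use [label_resistance()]).
#'
#' @param path TSV file.
#' @param pru_threshold Resistance threshold used for validation (PRU).
#' @return A tibble.
#' @export
read_phenotypes <- function(path, pru_threshold = 234) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "case", "pru")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("phenotype TSV lacks column(s): %s.", paste(miss, collapse = ", ")))
  bad_grp <- setdiff(unique(df$group), c("I", "II", "III", "IV"))
  if (length(bad_grp)) abort(sprintf("unknown group label(s): %s.", paste(bad_grp, collapse = ", ")))
  if (any(df$pru < 0, na.rm = TRUE)) abort("negative PRU values are invalid.")
  df$case <- as.logical(df$case)
  if ("resistance" %in% names(df)) {
    df$resistance <- as.logical(df$resistance)
    chk <- !is.na(df$resistance) & !is.na(df$pru) &
      df$resistance != (df$pru > pru_threshold)
    if (any(chk)) {
      abort(sprintf("resistance column contradicts PRU > %g rule for subject(s): %s.",
                    pru_threshold, paste(head(df$subject_id[chk], 5), collapse = ", ")))
    }
  } else {
    df$resistance <- NA
  }
  as_tibble(df)
}

#' Write a phenotype table
#'
#' @param pheno Phenotype tibble (see [read_phenotypes()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, na = "NA")
  invisible(path)
}

#' Read a SNP annotation table
#'
#' @param path TSV with columns `snp_id`, `chrom`, `pos`, `gene`.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("snp_id", "gene"), names(df))
  if (length(miss)) abort(sprintf("annotation TSV lacks column(s): %s.", paste(miss, collapse = ", ")))
  as_tibble(df)
}

#' Read a protein-protein interaction edge list
#'
#' Consumes a local BioGRID-style symbol-pair table with header columns
#' `symbol_a` and `symbol_b`. Self-loops are dropped with a message giving
#' the count.
#'
#' @param path Edge TSV.
#' @return A tibble with columns `symbol_a`, `symbol_b`.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(c("symbol_a", "symbol_b"), names(df))
  if (length(miss)) abort(sprintf("edge TSV lacks column(s): %s.", paste(miss, collapse = ", ")))
  loops <- df$symbol_a == df$symbol_b
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop edge(s).", sum(loops)))
    df <- df[!loops, ]
  }
  as_tibble(df[c("symbol_a", "symbol_b")])
}
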