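#' Genotype matrix container
#'
#' An additive-coded genotype matrix: subjects in rows, SNPs in columns,
#' values the count of alternate alleles (0, 1, 2) with `NA` marking a
#' missing call. Carries a per-SNP metadata tibble (chromosome, 1-based
#' position, reference and alternate alleles, and an optional gene symbol).
#' This is the one non-tibble container in the package; every operation on
#' it returns tibbles.
#'
#' @param calls Integer matrix, subjects x SNPs, values in \{0, 1, 2, NA\},
#'   with unique rownames (subject ids) and colnames (SNP ids).
#' @param snp_meta Optional tibble with columns `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene` matching `colnames(calls)`. When `NULL`, a
#'   placeholder is built (unknown chromosome/position, `ref = NA`).
#'
#' @return An object of class `snp_matrix`.
#' @export
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                 dimnames = list(c("s1", "s2"), c("snpA", "snpB")))
#' snp_matrix(calls)
snp_matrix <- function(calls, snp_meta = NULL) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix.")
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    abort("`calls` must have subject rownames and SNP colnames.")
  }
  if (anyDuplicated(rownames(calls))) abort("duplicate subject ids in `calls`.")
  if (anyDuplicated(colnames(calls))) abort("duplicate SNP ids in `calls`.")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    abort(sprintf("non-missing genotype calls must be 0, 1 or 2 (first offender: %s).",
                  calls[which(bad)[1]]))
  }
  if (is.null(snp_meta)) {
    snp_meta <- tibble(
      snp_id = colnames(calls),
      chrom  = NA_character_,
      pos    = NA_integer_,
      ref    = NA_character_,
      alt    = NA_character_,
      gene   = NA_character_
    )
  } else {
    snp_meta <- as_tibble(snp_meta)
    need <- c("snp_id", "chrom", "pos", "ref", "alt", "gene")
    miss <- setdiff(need, names(snp_meta))
    if (length(miss)) abort(sprintf("`snp_meta` lacks column(s): %s.", paste(miss, collapse = ", ")))
    if (!identical(snp_meta$snp_id, colnames(calls))) {
      abort("`snp_meta$snp_id` must match `colnames(calls)` in order.")
    }
    snp_meta <- snp_meta[need]
  }
  structure(list(calls = calls, snp_meta = snp_meta), class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d subjects x %d SNPs, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A [snp_matrix()].
#' @param i,j Subject and SNP indices (integer, logical or names).
#' @param ... Ignored.
#' @return A `snp_matrix` restricted to the selected subjects/SNPs.
#' @export
`[.snp_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  meta <- x$snp_meta[match(colnames(calls), x$snp_meta$snp_id), ]
  snp_matrix(calls, meta)
}

#' @export
as_tibble.snp_matrix <- function(x, ...) {
  tidy.snp_matrix(x)
}

#' Tidy a genotype matrix into long format
#'
#' @param x A [snp_matrix()].
#' @param ... Ignored.
#' @return A tibble with one row per (subject, SNP) cell: `subject_id`,
#'   `snp_id`, `call` (0/1/2/NA alternate-allele count).
#' @export
tidy.snp_matrix <- function(x, ...) {
  tibble(
    subject_id = rep(rownames(x$calls), times = ncol(x$calls)),
    snp_id     = rep(colnames(x$calls), each = nrow(x$calls)),
    call       = as.integer(x$calls)
  )
}

#' @export
glance.snp_matrix <- function(x, ...) {
  tibble(
    n_subjects   = nrow(x$calls),
    n_snps       = ncol(x$calls),
    missing_rate = mean(is.na(x$calls)),
    n_annotated  = sum(!is.na(x$snp_meta$gene) & x$snp_meta$gene != "")
  )
}

#' Coerce to a genotype matrix container
#'
#' @param x A `snp_matrix` (returned unchanged) or a subjects x SNPs matrix.
#' @return A `snp_matrix`.
#' @export
as_snp_matrix <- function(x) {
  if (inherits(x, "snp_matrix")) return(x)
  if (is.matrix(x)) return(snp_matrix(x))
  abort("cannot coerce this object to `snp_matrix`.")
}

# internal: bare integer matrix out of either representation
geno_calls <- function(x) {
  if (inherits(x, "snp_matrix")) x$calls else as_snp_matrix(x)$calls
}
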