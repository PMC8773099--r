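#' Specify a synthetic case/control genotyping cohort
#'
#' Parameters of the simulated study: diabetic PAD patients ("cases") and
#' age/sex-matched community controls genotyped on a SNP array, with a small
#' number of planted resistance-associated SNPs. Null SNPs share one allele
#' frequency in both arms; planted SNPs have their case-arm allele frequency
#' derived from the control frequency `p` and the allelic odds ratio `OR` as
#' `q = OR * p / (1 - p + OR * p)`.
#'
#' @param n_cases,n_controls Subjects per arm. Defaults 64/64, the size of
#'   the genotyped discovery cohort this generator emulates.
#' @param n_snps Number of array SNPs to simulate (array scale reduced to
#'   keep simulation tractable).
#' @param n_causal Number of planted resistance-associated SNPs.
#' @param causal_or Allelic odds ratio of each planted SNP (case vs control).
#' @param maf_range Length-2 vector: null allele frequencies are drawn
#'   uniformly from this interval (must lie in (0, 0.5]).
#' @param missing_rate Probability that any single call is missing,
#'   independently across cells. Must be < 1.
#' @param pru_mean_resistant,pru_mean_sensitive,pru_sd PRU phenotype model:
#'   cases draw PRU from Normal(`pru_mean_resistant`, `pru_sd`), controls
#'   from Normal(`pru_mean_sensitive`, `pru_sd`); draws are clipped at 0.
#'   Resistance labels are always recomputed from PRU (> 234), never stored
#'   independently.
#' @param causal_genes Optional character vector (length >= `n_causal`) of
#'   gene symbols assigned to the planted SNPs' metadata; other SNPs stay
#'   unannotated.
#' @param seed Integer seed governing all randomness of [simulate_cohort()].
#'
#' @return A list of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_cases = 64, n_controls = 64, n_snps = 2000,
                        n_causal = 3, causal_or = 15,
                        maf_range = c(0.05, 0.5), missing_rate = 0.02,
                        pru_mean_resistant = 300, pru_mean_sensitive = 160,
                        pru_sd = 50, causal_genes = NULL, seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg))
  }
  chk(is.numeric(n_cases) && n_cases >= 1, "n_cases", "must be a positive count")
  chk(is.numeric(n_controls) && n_controls >= 1, "n_controls", "must be a positive count")
  chk(is.numeric(n_snps) && n_snps >= 1, "n_snps", "must be a positive count")
  chk(is.numeric(n_causal) && n_causal >= 0, "n_causal", "must be a non-negative count")
  chk(n_causal <= n_snps, "n_causal", "cannot exceed n_snps")
  chk(is.numeric(causal_or) && causal_or > 0, "causal_or", "must be a positive real")
  chk(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2], "maf_range",
      "must be an increasing pair inside (0, 0.5]")
  chk(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
      "missing_rate", "must lie in [0, 1)")
  chk(is.numeric(pru_sd) && pru_sd > 0, "pru_sd", "must be positive")
  chk(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  if (!is.null(causal_genes)) {
    chk(length(causal_genes) >= n_causal, "causal_genes",
        "must supply at least n_causal gene symbols")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
         causal_or = causal_or, maf_range = maf_range,
         missing_rate = missing_rate,
         pru_mean_resistant = pru_mean_resistant,
         pru_mean_sensitive = pru_mean_sensitive, pru_sd = pru_sd,
         causal_genes = causal_genes, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Case-arm allele frequency implied by a control frequency and an odds ratio
#'
#' Inverts the allelic odds ratio: given control alternate-allele frequency
#' `p` and odds ratio `or`, returns `q` with odds(q) = or * odds(p).
#'
#' @param p Control-arm alternate-allele frequency in (0, 1).
#' @param or Allelic odds ratio.
#' @return Case-arm allele frequency.
#' @export
case_allele_freq <- function(p, or) {
  or * p / (1 - p + or * p)
}

#' Simulate a case/control genotyping cohort with planted risk SNPs
#'
#' Draws genotypes under Hardy-Weinberg equilibrium (per-subject calls are
#' Binomial(2, freq)), independently across SNPs (no linkage disequilibrium).
#' Missing calls are placed independently at `missing_rate`. PRU phenotypes
#' come from the resistant (cases) or sensitive (controls) normal component
#' and are clipped at 0; the resistance label is then recomputed from
#' PRU > 234 for cases so that PRU remains the single source of truth.
#'
#' All randomness flows from `spec$seed` with a fixed stream order (null
#' allele frequencies, causal SNP selection, genotype calls column-major,
#' missingness mask, PRU, group labels, covariates), so an identical spec
#' always reproduces byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `sim_cohort` with elements `genotypes`
#'   ([snp_matrix()]), `phenotypes` (tibble: `subject_id`, `group` I-IV,
#'   `case`, `pru`, `resistance`, `sex`, `age`), `causal_snps` (character
#'   vector of planted SNP ids), and `allele_freqs` (tibble of the drawn
#'   per-SNP control/case allele frequencies).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_cases = 20, n_controls = 20,
#'                                       n_snps = 50, n_causal = 2, seed = 7))
#' cohort$causal_snps
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, as.list(spec))
  n_sub <- spec$n_cases + spec$n_controls
  withr::with_seed(spec$seed, {
    p_null <- runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
    causal_idx <- if (spec$n_causal > 0) sort(sample.int(spec$n_snps, spec$n_causal)) else integer(0)
    q_case <- p_null
    q_case[causal_idx] <- case_allele_freq(p_null[causal_idx], spec$causal_or)

    case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))
    freq <- rbind(
      matrix(q_case, nrow = spec$n_cases, ncol = spec$n_snps, byrow = TRUE),
      matrix(p_null, nrow = spec$n_controls, ncol = spec$n_snps, byrow = TRUE)
    )
    calls <- matrix(rbinom(n_sub * spec$n_snps, 2L, as.vector(freq)),
                    nrow = n_sub, ncol = spec$n_snps)
    if (spec$missing_rate > 0) {
      calls[matrix(runif(n_sub * spec$n_snps) < spec$missing_rate,
                   nrow = n_sub)] <- NA_integer_
    }
    pru_mean <- ifelse(case, spec$pru_mean_resistant, spec$pru_mean_sensitive)
    pru <- pmax(0, rnorm(n_sub, pru_mean, spec$pru_sd))
    group <- c(sample(c("I", "II", "III"), spec$n_cases, replace = TRUE,
                      prob = c(21, 24, 19) / 64),
               rep("IV", spec$n_controls))
    sex <- sample(c("male", "female"), n_sub, replace = TRUE, prob = c(0.65, 0.35))
    age <- round(rnorm(n_sub, 64, 10))
  })

  snp_ids <- sprintf("snp%05d", seq_len(spec$n_snps))
  subject_ids <- sprintf("subj%04d", seq_len(n_sub))
  dimnames(calls) <- list(subject_ids, snp_ids)

  gene <- rep(NA_character_, spec$n_snps)
  if (!is.null(spec$causal_genes) && spec$n_causal > 0) {
    gene[causal_idx] <- spec$causal_genes[seq_len(spec$n_causal)]
  }
  meta <- tibble(
    snp_id = snp_ids,
    chrom  = as.character(rep_len(1:22, spec$n_snps)),
    pos    = as.integer(seq_len(spec$n_snps) * 1000L),
    ref    = "A",
    alt    = "G",
    gene   = gene
  )

  pheno <- tibble(
    subject_id = subject_ids,
    group = group,
    case = case,
    pru = pru,
    resistance = NA,
    sex = sex,
    age = age
  )
  pheno <- label_resistance(pheno)

  structure(
    list(genotypes = snp_matrix(calls, meta),
         phenotypes = pheno,
         causal_snps = snp_ids[causal_idx],
         allele_freqs = tibble(snp_id = snp_ids, control_freq = p_null,
                               case_freq = q_case,
                               causal = seq_len(spec$n_snps) %in% causal_idx),
         spec = spec),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d cases / %d controls, %d SNPs (%d planted, OR = %g)\n",
              x$spec$n_cases, x$spec$n_controls, x$spec$n_snps,
              x$spec$n_causal, x$spec$causal_or))
  invisible(x)
}

#' @export
glance.sim_cohort <- function(x, ...) {
  tibble(
    n_cases = x$spec$n_cases, n_controls = x$spec$n_controls,
    n_snps = x$spec$n_snps, n_causal = x$spec$n_causal,
    causal_or = x$spec$causal_or, seed = x$spec$seed,
    missing_rate_observed = mean(is.na(x$genotypes$calls)),
    resistant_cases = sum(x$phenotypes$resistance, na.rm = TRUE)
  )
}
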