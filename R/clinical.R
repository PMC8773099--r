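fisher_exact_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d)))) {
    abort("counts must be non-negative integers.")
  }
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warn("table has a zero margin; p = 1 by convention.")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  pr <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  # two-sided rule: sum point probabilities <= observed (with tie tolerance)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Fisher's exact test (two-sided) on 2x2 tables
#'
#' Exact hypergeometric enumeration over the table's support. The two-sided
#' p-value sums the point probabilities of all tables (with the observed
#' margins) no more probable than the observed one, with a relative
#' tolerance of 1e-7 for ties — the convention under which the trial's
#' printed medication-use p-values (0.034, 0.036) reproduce. A zero row or
#' column margin returns p = 1 with a warning.
#'
#' Methods: a 2x2 `matrix`; a length-4 numeric `(a, b, c, d)` filled
#' row-wise; or a data frame with columns `a`, `b`, `c`, `d` (one table per
#' row, batch mode).
#'
#' @param x Table(s) to test.
#' @param ... Passed between methods.
#' @return One-row tibble (`p_value`, `odds_ratio`, `method`) for a single
#'   table; for a data frame, the input with a `p_value` column appended.
#' @export
#' @examples
#' fisher_exact(c(16, 5, 10, 14))  # prints as 0.034 at 3 decimals
fisher_exact <- function(x, ...) UseMethod("fisher_exact")

#' @rdname fisher_exact
#' @export
fisher_exact.matrix <- function(x, ...) {
  if (!all(dim(x) == c(2, 2))) abort("`x` must be a 2x2 matrix.")
  fisher_exact.numeric(c(t(x)))
}

#' @rdname fisher_exact
#' @export
fisher_exact.numeric <- function(x, ...) {
  if (length(x) != 4) abort("`x` must have four counts (a, b, c, d).")
  tibble(
    p_value = fisher_exact_p(x[1], x[2], x[3], x[4]),
    odds_ratio = odds_ratio_2x2(matrix(x, 2, byrow = TRUE)),
    method = "Fisher exact, two-sided"
  )
}

#' @rdname fisher_exact
#' @export
fisher_exact.data.frame <- function(x, ...) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(x))) abort("data frame needs columns a, b, c, d.")
  x$p_value <- pmap(x[need], function(a, b, c, d) fisher_exact_p(a, b, c, d)) |>
    unlist()
  as_tibble(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midrank sums. With 12 or fewer observations in total
#' and no ties the p-value is exact (full enumeration of rank assignments);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Two identical samples give p = 1.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty.")
  m <- length(x); n <- length(y); N <- m + n
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)

  if (N <= 12 && !has_ties) {
    combos <- utils::combn(N, m)
    r_all <- rank(all_v)  # no ties: a permutation of 1..N
    Us <- apply(combos, 2, function(idx) sum(r_all[idx])) - m * (m + 1) / 2
    cdf_lo <- mean(Us <= U); cdf_hi <- mean(Us >= U)
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
    method <- "Mann-Whitney U, exact"
  } else {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 == 0) {
      return(tibble(statistic = U, p_value = 1,
                    method = "Mann-Whitney U, degenerate (all values tied)"))
    }
    z <- U - m * n / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Mann-Whitney U, normal approximation"
  }
  tibble(statistic = U, p_value = p, method = method)
}

#' Sample size for comparing two proportions
#'
#' Normal-approximation two-group sample size with pooled variance under
#' the null and no continuity correction:
#' `n = (z_{1-alpha/2} sqrt(2 p.bar q.bar) + z_{power} sqrt(p1 q1 + p2 q2))^2 / (p1 - p2)^2`,
#' rounded to the nearest integer per group. The enrolment target inflates
#' the evaluable total for anticipated attrition: `floor(n_total / (1 - loss))`.
#' With the trial's planning values (70% vs 30% event rate, two-sided
#' alpha 0.05, power 0.80, 15% loss) this gives 23 per group, 46 evaluable,
#' 54 enrolled.
#'
#' @param p1,p2 Anticipated proportions (distinct, in (0, 1)).
#' @param alpha Two-sided type-I error rate.
#' @param power Target power (1 - beta).
#' @param loss Anticipated attrition fraction in `[0, 1)`.
#' @return One-row tibble: `n_per_group`, `n_total`, `n_enrolled`,
#'   `n_raw` (unrounded per-group requirement).
#' @export
#' @examples
#' sample_size_two_proportions(0.70, 0.30, loss = 0.15)
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80,
                                        loss = 0) {
  if (!(p1 > 0 && p1 < 1 && p2 > 0 && p2 < 1)) abort("p1 and p2 must lie in (0, 1).")
  if (p1 == p2) abort("p1 must differ from p2 (otherwise n is infinite).")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1).")
  if (!(power > 0 && power < 1)) abort("power must lie in (0, 1).")
  if (!(loss >= 0 && loss < 1)) abort("loss must lie in [0, 1).")
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2); zb <- qnorm(power)
  n_raw <- (za * sqrt(2 * pbar * (1 - pbar)) +
              zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  n_per_group <- round(n_raw)
  n_total <- 2L * n_per_group
  tibble(
    n_per_group = n_per_group,
    n_total = n_total,
    n_enrolled = as.integer(floor(n_total / (1 - loss))),
    n_raw = n_raw
  )
}
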