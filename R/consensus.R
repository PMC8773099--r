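#' Stratified train/validation re-splits for bootstrapped ranking
#'
#' Generates `n_iterations` independent label-stratified splits of the
#' subjects into a training fraction and its complementary validation set.
#' The per-class training counts follow the largest-remainder rule so the
#' total training size is `round(train_fraction * n)` whenever the class
#' sizes allow it. With `replace = TRUE` the training set is drawn with
#' replacement within class (a classical bootstrap) and the validation set
#' is the out-of-bag remainder.
#'
#' @param labels Logical (or two-level) label vector, NA-free.
#' @param n_iterations Number of splits (default 100).
#' @param train_fraction Training fraction in (0, 1) (default 0.8).
#' @param replace Draw the training set with replacement (default `FALSE`,
#'   i.e. repeated random sub-sampling).
#' @param seed Integer seed; identical seed and arguments reproduce the
#'   identical split sequence.
#' @return A list of length `n_iterations`; each element is a list with
#'   integer index vectors `train` and `validation` (disjoint).
#' @export
bootstrap_splits <- function(labels, n_iterations = 100, train_fraction = 0.8,
                             replace = FALSE, seed = 1L) {
  if (anyNA(labels)) abort("`labels` must not contain NA.")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < 10) abort("need at least 10 labelled subjects to split.")
  cls <- split(seq_len(n), labels)
  if (any(lengths(cls) < 2)) abort("each label class needs at least 2 subjects.")

  # largest-remainder apportionment of the training quota across classes
  quota <- train_fraction * lengths(cls)
  k <- floor(quota)
  total <- round(train_fraction * n)
  short <- total - sum(k)
  if (short > 0) {
    extra <- order(quota - k, decreasing = TRUE)[seq_len(short)]
    k[extra] <- k[extra] + 1
  }
  k <- pmin(pmax(k, 1), lengths(cls) - 1)  # both sides non-empty per class

  withr::with_seed(seed, {
    lapply(seq_len(n_iterations), function(i) {
      tr <- unlist(map2(cls, k, function(idx, kk) {
        sample(idx, kk, replace = replace)
      }), use.names = FALSE)
      list(train = sort(tr), validation = sort(setdiff(seq_len(n), tr)))
    })
  })
}

# per-SNP mode imputation (ties -> smaller genotype; all-missing -> 0)
impute_mode <- function(X) {
  nas <- colSums(is.na(X))
  for (j in which(nas > 0)) {
    v <- X[, j]
    obs <- v[!is.na(v)]
    fill <- if (length(obs) == 0) 0L else which.max(tabulate(obs + 1L, 3L)) - 1L
    v[is.na(v)] <- fill
    X[, j] <- v
  }
  X
}

# column standardization; constant columns become all-zero
standardize_cols <- function(X, center = NULL, scale = NULL) {
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- Inf
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

#' Rank SNPs by importance under one learner
#'
#' Fits a single learner on a (training) genotype matrix and returns all
#' SNP ids ordered from most to least important. Missing genotypes are
#' mode-imputed per SNP beforehand; genotypes are standardized for the SVM
#' and LASSO (the forest uses raw additive codes). Importance scores:
#' impurity importance (`forest`, 500 trees), absolute weight of a
#' linear-kernel fit (`svm`, cost 1), and absolute coefficient at the
#' cross-validated penalty (`lasso`; zero coefficients rank last). Ties —
#' including degenerate constant features, which score 0 — break by
#' ascending SNP id.
#'
#' @param X Numeric training matrix (subjects x SNPs) with colnames.
#' @param y Logical/two-level label vector for the rows of `X`.
#' @param method `"forest"`, `"svm"` or `"lasso"`.
#' @param seed Integer seed for the learner's internal randomness.
#' @param num_trees Forest size.
#' @param svm_cost Linear SVM cost parameter.
#' @param lasso_nfolds Cross-validation folds for the LASSO penalty.
#' @return Character vector of SNP ids, most important first.
#' @export
rank_snps_once <- function(X, y, method = c("forest", "svm", "lasso"),
                           seed = 1L, num_trees = 500, svm_cost = 1,
                           lasso_nfolds = 5) {
  method <- match.arg(method)
  ids <- colnames(X)
  if (is.null(ids)) abort("`X` must have SNP colnames.")
  X <- impute_mode(X)
  y <- factor(as.logical(y), levels = c(FALSE, TRUE))

  score <- switch(method,
    forest = {
      fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      imp <- fit$variable.importance
      imp[ids]
    },
    svm = {
      Xs <- standardize_cols(X)
      fit <- e1071::svm(x = Xs, y = y, kernel = "linear", cost = svm_cost,
                        scale = FALSE)
      w <- as.vector(crossprod(fit$coefs, fit$SV))
      stats::setNames(abs(w), colnames(Xs))[ids]
    },
    lasso = {
      foldid <- withr::with_seed(seed, sample(rep(seq_len(lasso_nfolds),
                                                  length.out = nrow(X))))
      fit <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                               nlambda = 40, lambda.min.ratio = 0.05,
                               standardize = TRUE)
      beta <- as.vector(stats::coef(fit, s = "lambda.min"))[-1]
      stats::setNames(abs(beta), colnames(X))[ids]
    }
  )
  score[is.na(score)] <- 0
  ids[order(-score, ids)]
}

#' Aggregate per-iteration top sets into a consensus ranking
#'
#' The consensus count of a SNP is the number of (iteration, method) pairs
#' whose top-k set contains it; SNPs are ranked by descending count with
#' ties broken by ascending SNP id.
#'
#' @param top_sets Tibble with columns `iteration`, `method`, `snp_id`
#'   (one row per top-set membership).
#' @param snp_ids All candidate SNP ids (zero-count SNPs are kept).
#' @return Tibble: `snp_id`, `count`, `rank`.
#' @export
aggregate_counts <- function(top_sets, snp_ids) {
  counts <- top_sets %>%
    dplyr::count(.data$snp_id, name = "count")
  tibble(snp_id = snp_ids) %>%
    left_join(counts, by = "snp_id") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    arrange(desc(.data$count), .data$snp_id) %>%
    mutate(rank = row_number())
}

#' Bootstrapped three-learner consensus SNP ranking
#'
#' Stage 2 of the signature discovery pipeline: the labelled cohort is
#' re-split `n_iterations` times into stratified 80/20 train/validation
#' sets; on every training set each learner ranks all SNPs and its top
#' `top_k` are recorded; a SNP's consensus count is the number of
#' (iteration, method) top sets containing it, bounded by
#' `n_iterations * length(methods)`. Identical inputs and seed reproduce
#' the identical ranking.
#'
#' @param x A [snp_matrix()] or matrix (typically the association-filtered
#'   SNPs).
#' @param labels Named logical label vector (see [association_labels()]),
#'   or an unnamed vector aligned with the rows of `x`.
#' @param n_iterations Number of bootstrap re-splits (default 100).
#' @param train_fraction Training fraction (default 0.8).
#' @param top_k Top-set size per learner per iteration (default 20, the
#'   size of the reported signature pool).
#' @param methods Subset of `c("forest", "svm", "lasso")`.
#' @param replace Passed to [bootstrap_splits()].
#' @param seed Master seed for splits and learners.
#' @param num_trees,svm_cost,lasso_nfolds Learner hyperparameters, see
#'   [rank_snps_once()].
#' @return A list of class `consensus_ranking`: `counts` (tibble `snp_id`,
#'   `count`, `rank`), `top_sets` (long per-iteration log), `params`.
#' @export
consensus_rank <- function(x, labels, n_iterations = 100, train_fraction = 0.8,
                           top_k = 20, methods = c("forest", "svm", "lasso"),
                           replace = FALSE, seed = 1L, num_trees = 500,
                           svm_cost = 1, lasso_nfolds = 5) {
  x <- as_snp_matrix(x)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(names(labels))) {
    common <- intersect(rownames(x$calls), names(labels[!is.na(labels)]))
    calls <- x$calls[common, , drop = FALSE]
    y <- as.logical(labels[common])
  } else {
    if (length(labels) != nrow(x$calls)) {
      abort("unnamed `labels` must align with the rows of `x`.")
    }
    calls <- x$calls
    y <- as.logical(labels)
  }
  if (top_k > ncol(calls)) abort("`top_k` cannot exceed the number of SNPs.")

  splits <- bootstrap_splits(y, n_iterations, train_fraction,
                             replace = replace, seed = seed)
  seed_tab <- withr::with_seed(seed, {
    matrix(sample.int(1e8, n_iterations * length(methods)),
           nrow = n_iterations,
           dimnames = list(NULL, methods))
  })

  top_sets <- bind_rows(lapply(seq_len(n_iterations), function(i) {
    tr <- splits[[i]]$train
    Xtr <- calls[tr, , drop = FALSE]
    ytr <- y[tr]
    bind_rows(lapply(methods, function(m) {
      ord <- rank_snps_once(Xtr, ytr, method = m, seed = seed_tab[i, m],
                            num_trees = num_trees, svm_cost = svm_cost,
                            lasso_nfolds = lasso_nfolds)
      tibble(iteration = i, method = m, snp_id = head(ord, top_k))
    }))
  }))

  structure(
    list(counts = aggregate_counts(top_sets, colnames(calls)),
         top_sets = top_sets,
         params = list(n_iterations = n_iterations,
                       train_fraction = train_fraction, top_k = top_k,
                       methods = methods, replace = replace, seed = seed,
                       num_trees = num_trees, svm_cost = svm_cost,
                       lasso_nfolds = lasso_nfolds)),
    class = "consensus_ranking"
  )
}

#' @export
print.consensus_ranking <- function(x, ...) {
  p <- x$params
  cat(sprintf("<consensus_ranking> %d SNPs, %d iterations x {%s}, top_k = %d\n",
              nrow(x$counts), p$n_iterations,
              paste(p$methods, collapse = ", "), p$top_k))
  print(head(x$counts, 10))
  invisible(x)
}

#' @export
tidy.consensus_ranking <- function(x, ...) x$counts

#' @export
glance.consensus_ranking <- function(x, ...) {
  p <- x$params
  tibble(
    n_snps = nrow(x$counts),
    n_iterations = p$n_iterations,
    n_methods = length(p$methods),
    top_k = p$top_k,
    max_count = max(x$counts$count),
    total_count = sum(x$counts$count)
  )
}
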