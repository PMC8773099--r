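#' Area under the ROC curve by the rank statistic
#'
#' Computes AUC as the normalized Mann-Whitney statistic with midranks for
#' ties: `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum
#' of the positive-class scores. Identical to trapezoidal integration of the
#' empirical ROC curve.
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Logical vector, `TRUE` = positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# fit one evaluation model on train and return positive-class probabilities
# on the validation matrix; `seed` controls learner randomness
fit_predict_prob <- function(model, Xtr, ytr, Xval, seed = 1L,
                             num_trees = 500, svm_cost = 1, xgb_nrounds = 50) {
  yf <- factor(as.logical(ytr), levels = c(FALSE, TRUE))
  switch(model,
    forest = {
      fit <- ranger::ranger(x = Xtr, y = yf, num.trees = num_trees,
                            probability = TRUE, seed = seed, num.threads = 1)
      predict(fit, data = Xval, num.threads = 1)$predictions[, "TRUE"]
    },
    svm = {
      Xs <- standardize_cols(Xtr)
      Xv <- standardize_cols(Xval, center = attr(Xs, "center"),
                             scale = attr(Xs, "scale"))
      fit <- e1071::svm(x = Xs, y = yf, kernel = "linear", cost = svm_cost,
                        scale = FALSE)
      dvm <- attr(predict(fit, Xv, decision.values = TRUE), "decision.values")
      dv <- dvm[, 1]
      # positive decision values favor the class named first in the colname
      if (startsWith(colnames(dvm)[1], "FALSE")) dv <- -dv
      stats::plogis(dv)
    },
    tree = {
      df <- data.frame(y = yf, Xtr, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      predict(fit, newdata = data.frame(Xval, check.names = FALSE),
              type = "prob")[, "TRUE"]
    },
    xgboost = {
      fit <- xgboost::xgboost(Xtr, yf, nrounds = xgb_nrounds, nthreads = 1,
                              objective = "binary:logistic", seed = seed,
                              verbosity = 0)
      p2 <- predict(fit, Xval, type = "response")
      p2
    },
    abort(sprintf("unknown model '%s'.", model))
  )
}

#' AUC/accuracy curve over the number of top-ranked SNPs
#'
#' Stage 3 of the signature discovery pipeline: for each evaluation model
#' and each feature count `k = 1..max_features`, fits the model on the
#' training portion of every split using the `k` highest-consensus SNPs and
#' scores it on the held-out validation portion; AUC and accuracy
#' (probability threshold 0.5) are averaged across splits. Supplying an
#' annotation table restricts the ranking to SNPs mapped to a gene before
#' the sweep (the "annotated SNPs only" reduction).
#'
#' @param x A [snp_matrix()] or matrix containing at least the ranked SNPs.
#' @param labels Named or aligned logical label vector (see
#'   [consensus_rank()]).
#' @param ranking A [consensus_rank()] result, a tibble with a ranked
#'   `snp_id` column, or a character vector of SNP ids in rank order.
#' @param models Subset of `c("forest", "svm", "tree", "xgboost")` (the
#'   four evaluation classifiers; default all four).
#' @param max_features Largest feature count swept (error if it exceeds the
#'   ranked SNPs available).
#' @param n_iterations,train_fraction,splits Evaluation splits: either pass
#'   `splits` from [bootstrap_splits()] (e.g. to reuse the ranking folds) or
#'   let the function generate `n_iterations` stratified splits.
#' @param seed Seed for split generation and learner randomness.
#' @param tolerance AUC tolerance handed to [select_signature()].
#' @param annotation Optional tibble with `snp_id`, `gene`; when given,
#'   only SNPs with a non-empty gene symbol enter the sweep.
#' @param num_trees,svm_cost,xgb_nrounds Model hyperparameters.
#' @return A list of class `eval_curve`: `curve` (tibble `model`,
#'   `n_features`, `auc`, `accuracy`, `auc_sd`, `accuracy_sd`), `snp_order`,
#'   `selection` (list from [select_signature()]), `params`.
#' @export
evaluate_curve <- function(x, labels, ranking,
                           models = c("forest", "svm", "tree", "xgboost"),
                           max_features = 10, n_iterations = 20,
                           train_fraction = 0.8, splits = NULL, seed = 1L,
                           tolerance = 0.005, annotation = NULL,
                           num_trees = 500, svm_cost = 1, xgb_nrounds = 50) {
  x <- as_snp_matrix(x)
  models <- match.arg(models, several.ok = TRUE)
  ranked <- if (inherits(ranking, "consensus_ranking")) {
    ranking$counts$snp_id
  } else if (is.data.frame(ranking)) {
    ranking$snp_id
  } else {
    as.character(ranking)
  }
  if (!is.null(annotation)) {
    keep <- annotation$snp_id[!is.na(annotation$gene) & annotation$gene != ""]
    ranked <- ranked[ranked %in% keep]
  }
  ranked <- ranked[ranked %in% colnames(x$calls)]
  if (max_features > length(ranked)) {
    abort(sprintf("`max_features` (%d) exceeds the %d ranked SNPs available.",
                  max_features, length(ranked)))
  }

  if (!is.null(names(labels))) {
    common <- intersect(rownames(x$calls), names(labels[!is.na(labels)]))
    calls <- x$calls[common, ranked, drop = FALSE]
    y <- as.logical(labels[common])
  } else {
    calls <- x$calls[, ranked, drop = FALSE]
    y <- as.logical(labels)
  }
  if (is.null(splits)) {
    splits <- bootstrap_splits(y, n_iterations, train_fraction, seed = seed)
  }
  seed_tab <- withr::with_seed(seed, {
    matrix(sample.int(1e8, length(splits) * length(models)),
           nrow = length(splits), dimnames = list(NULL, models))
  })

  res <- bind_rows(lapply(seq_along(splits), function(i) {
    tr <- splits[[i]]$train; va <- splits[[i]]$validation
    Xtr_full <- impute_mode(calls[tr, , drop = FALSE])
    # validation imputed with training modes by imputing jointly per column
    Xva_full <- calls[va, , drop = FALSE]
    for (j in seq_len(ncol(Xva_full))) {
      nas <- is.na(Xva_full[, j])
      if (any(nas)) {
        obs <- Xtr_full[, j]
        Xva_full[nas, j] <- which.max(tabulate(obs + 1L, 3L)) - 1L
      }
    }
    ytr <- y[tr]; yva <- y[va]
    bind_rows(lapply(models, function(m) {
      bind_rows(lapply(seq_len(max_features), function(k) {
        prob <- fit_predict_prob(m, Xtr_full[, seq_len(k), drop = FALSE], ytr,
                                 Xva_full[, seq_len(k), drop = FALSE],
                                 seed = seed_tab[i, m], num_trees = num_trees,
                                 svm_cost = svm_cost, xgb_nrounds = xgb_nrounds)
        tibble(split = i, model = m, n_features = k,
               auc = auc_rank(prob, yva),
               accuracy = mean((prob > 0.5) == yva))
      }))
    }))
  }))

  curve <- res %>%
    group_by(.data$model, .data$n_features) %>%
    summarise(auc_sd = sd(.data$auc), accuracy_sd = sd(.data$accuracy),
              auc = mean(.data$auc), accuracy = mean(.data$accuracy),
              .groups = "drop") %>%
    select("model", "n_features", "auc", "accuracy", "auc_sd", "accuracy_sd")

  out <- structure(
    list(curve = curve, snp_order = head(ranked, max_features),
         selection = NULL,
         params = list(models = models, max_features = max_features,
                       n_splits = length(splits), seed = seed,
                       tolerance = tolerance)),
    class = "eval_curve"
  )
  out$selection <- select_signature(out, tolerance = tolerance)
  out
}

#' Select the signature: minimum feature count within tolerance of the best AUC
#'
#' Formalizes "the minimum needed feature number": the selected feature
#' count is the smallest `k` whose best-model AUC is within `tolerance` of
#' the global maximum over all (model, k) pairs; the selected model is the
#' AUC argmax at that `k`, ties broken by fewer features first and then by
#' model name order. Deterministic given a curve.
#'
#' @param curve An `eval_curve` object or its `curve` tibble.
#' @param tolerance Absolute AUC tolerance (default 0.005).
#' @return A list: `model`, `n_features`, `auc`, `accuracy`, and — when a
#'   full `eval_curve` is supplied — the selected `snp_ids`.
#' @export
select_signature <- function(curve, tolerance = 0.005) {
  obj <- NULL
  if (inherits(curve, "eval_curve")) {
    obj <- curve
    curve <- curve$curve
  }
  best_k <- curve %>%
    group_by(.data$n_features) %>%
    summarise(auc = max(.data$auc), .groups = "drop")
  gmax <- max(best_k$auc)
  k_star <- min(best_k$n_features[best_k$auc >= gmax - tolerance])
  at_k <- curve %>%
    filter(.data$n_features == k_star) %>%
    arrange(desc(.data$auc), .data$model) %>%
    slice(1)
  out <- list(model = at_k$model, n_features = k_star,
              auc = at_k$auc, accuracy = at_k$accuracy)
  if (!is.null(obj)) out$snp_ids <- head(obj$snp_order, k_star)
  out
}

#' @export
print.eval_curve <- function(x, ...) {
  s <- x$selection
  cat(sprintf("<eval_curve> %d models x %d feature counts over %d splits\n",
              length(x$params$models), x$params$max_features, x$params$n_splits))
  cat(sprintf("selected: %s with %d SNP(s), AUC = %.3f, accuracy = %.3f\n",
              s$model, s$n_features, s$auc, s$accuracy))
  invisible(x)
}

#' @export
tidy.eval_curve <- function(x, ...) x$curve

#' @export
glance.eval_curve <- function(x, ...) {
  s <- x$selection
  tibble(selected_model = s$model, selected_n_features = s$n_features,
         auc = s$auc, accuracy = s$accuracy,
         n_models = length(x$params$models),
         max_features = x$params$max_features, n_splits = x$params$n_splits)
}

#' Genotype-frequency chi-square test for one SNP
#'
#' Compares the genotype distribution (0/1/2 alternate-allele counts)
#' between two groups — typically resistant vs non-resistant patients —
#' with an uncorrected Pearson chi-square on the 2 x 3 table. Genotype
#' columns absent from both groups are dropped with the degrees of freedom
#' reduced accordingly; fewer than two non-empty genotype columns make the
#' SNP untestable.
#'
#' @param calls Additive genotype vector (0/1/2/NA).
#' @param labels Logical group vector aligned with `calls`.
#' @return A list: `table` (groups x genotypes counts), `chi2`, `df`,
#'   `p_value`, `untestable`.
#' @export
genotype_frequency_test <- function(calls, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(calls) & !is.na(labels)
  tab <- table(factor(labels[ok], levels = c(TRUE, FALSE)),
               factor(calls[ok], levels = 0:2))
  tab <- unclass(tab)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
    return(list(table = tab, chi2 = NA_real_, df = NA_integer_,
                p_value = NA_real_, untestable = TRUE))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(table = tab, chi2 = chi2, df = df,
       p_value = pchisq(chi2, df = df, lower.tail = FALSE),
       untestable = FALSE)
}

#' Genotype-frequency comparison across many SNPs
#'
#' Tidy batch form of [genotype_frequency_test()] for a set of signature
#' SNPs, contrasting resistant vs non-resistant patients by default.
#'
#' @param x A [snp_matrix()] or matrix.
#' @param pheno Phenotype tibble or named logical label vector.
#' @param snp_ids SNPs to test (default: all columns of `x`).
#' @param contrast Passed to [association_labels()] when `pheno` is a table.
#' @return A tibble with one row per SNP: genotype counts per group
#'   (`g0_1`, `g1_1`, `g2_1` for the `TRUE` group and `_0` for the other),
#'   `chi2`, `df`, `p_value`, `untestable`.
#' @export
test_genotype_frequencies <- function(x, pheno, snp_ids = NULL,
                                      contrast = c("resistance", "case_control")) {
  x <- as_snp_matrix(x)
  lab <- if (is.data.frame(pheno)) {
    association_labels(pheno, match.arg(contrast))
  } else {
    pheno[!is.na(pheno)]
  }
  common <- intersect(rownames(x$calls), names(lab))
  calls <- x$calls[common, , drop = FALSE]
  lab <- as.logical(lab[common])
  snp_ids <- snp_ids %||% colnames(calls)

  bind_rows(lapply(snp_ids, function(id) {
    res <- genotype_frequency_test(calls[, id], lab)
    full <- matrix(0L, 2, 3, dimnames = list(c("TRUE", "FALSE"), 0:2))
    full[, colnames(res$table)] <- res$table
    tibble(snp_id = id,
           g0_1 = full[1, 1], g1_1 = full[1, 2], g2_1 = full[1, 3],
           g0_0 = full[2, 1], g1_0 = full[2, 2], g2_0 = full[2, 3],
           chi2 = res$chi2, df = res$df, p_value = res$p_value,
           untestable = res$untestable)
  }))
}
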