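#' Plot an AUC/accuracy feature-number curve
#'
#' Performance of each evaluation model against the number of top-ranked
#' SNPs included, one panel per metric.
#'
#' @param object An [evaluate_curve()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.eval_curve <- function(object, ...) {
  dat <- object$curve %>%
    tidyr::pivot_longer(c("auc", "accuracy"), names_to = "metric",
                        values_to = "value") %>%
    mutate(metric = dplyr::recode(.data$metric, auc = "AUC",
                                  accuracy = "Accuracy"))
  sel <- object$selection
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_features, y = .data$value,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_vline(xintercept = sel$n_features, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(breaks = unique(dat$n_features)) +
    ggplot2::labs(x = "Number of top-ranked SNPs", y = NULL, colour = "Model",
                  title = "Validation performance vs signature size",
                  subtitle = sprintf("selected: %s, %d SNP(s)",
                                     sel$model, sel$n_features)) +
    ggplot2::theme_minimal()
}

#' Plot a consensus ranking
#'
#' Consensus counts of the top-ranked SNPs (number of bootstrap iteration x
#' learner top sets containing each SNP).
#'
#' @param object A [consensus_rank()] result.
#' @param top_n How many leading SNPs to show.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.consensus_ranking <- function(object, top_n = 20, ...) {
  dat <- head(object$counts, top_n)
  cap <- object$params$n_iterations * length(object$params$methods)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$snp_id, .data$count),
                                    y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = cap, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("Consensus count (max %d)", cap),
                  title = "Bootstrapped consensus SNP ranking") +
    ggplot2::theme_minimal()
}

#' Plot a protein-interaction subnetwork
#'
#' Signature genes and their bridge proteins with a deterministic
#' force-directed layout.
#'
#' @param object A [build_subnetwork()] result.
#' @param layout_seed Seed for the layout.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ppi_subnetwork <- function(object, layout_seed = 1L, ...) {
  g <- object$graph
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble(symbol = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) %>%
    left_join(object$nodes, by = "symbol")
  edges <- object$edges %>%
    left_join(nodes[c("symbol", "x", "y")], by = c(symbol_a = "symbol")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(nodes[c("symbol", "x", "y")], by = c(symbol_b = "symbol"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$role), size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$symbol),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_manual(values = c(signature = "firebrick",
                                            bridge = "steelblue")) +
    ggplot2::labs(colour = NULL, title = "Signature protein-interaction subnetwork") +
    ggplot2::theme_void()
}

#' Plot genotype-frequency comparisons between groups
#'
#' Stacked genotype proportions per SNP and group, the bar-chart analogue of
#' a per-SNP genotype pie panel.
#'
#' @param freqs Tibble from [test_genotype_frequencies()].
#' @param group_labels Length-2 labels for the `TRUE` and `FALSE` groups.
#' @return A ggplot object.
#' @export
plot_genotype_frequencies <- function(freqs,
                                      group_labels = c("resistant", "non-resistant")) {
  dat <- freqs %>%
    tidyr::pivot_longer(dplyr::matches("^g[012]_[01]$"),
                        names_to = c("genotype", "grp"), names_pattern = "g([012])_([01])",
                        values_to = "count") %>%
    mutate(group = ifelse(.data$grp == "1", group_labels[1], group_labels[2]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$count,
                                    fill = .data$genotype)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::facet_wrap(~snp_id) +
    ggplot2::labs(x = NULL, y = "Genotype proportion", fill = "Alt alleles") +
    ggplot2::theme_minimal()
}
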