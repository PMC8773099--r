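#' Default gene-symbol alias table
#'
#' Known alternate spellings resolved before matching signature genes to the
#' interaction edge list (e.g. `LRBA1` for `LRBA`). Names are aliases,
#' values the canonical symbols.
#'
#' @return Named character vector.
#' @export
default_gene_aliases <- function() {
  c(LRBA1 = "LRBA")
}

canon_symbols <- function(x, aliases) {
  x <- toupper(x)
  hit <- match(x, toupper(names(aliases)))
  x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  x
}

#' Build the protein-interaction subnetwork around a SNP signature
#'
#' From a local protein-protein interaction edge list, extracts the
#' signature genes plus every "bridge" protein lying on a path of length at
#' most `max_path_length` between two distinct signature genes, with the
#' edges induced among the included nodes. Signature genes absent from the
#' edge list are retained as isolated (degree 0) nodes with a warning.
#' Symbol matching is case-insensitive after alias resolution.
#'
#' @param edges Tibble with columns `symbol_a`, `symbol_b` (see
#'   [read_edge_list()]), or a path to such a TSV.
#' @param signature_genes Character vector of signature gene symbols.
#' @param max_path_length Maximum signature-to-signature path length through
#'   a bridge node (default 2, i.e. single intermediates).
#' @param aliases Named character alias table (default
#'   [default_gene_aliases()]).
#' @return A list of class `ppi_subnetwork`: `nodes` (tibble `symbol`,
#'   `role` in signature/bridge, `degree`, `component`), `edges` (tibble),
#'   `graph` (igraph object), `signature_genes`.
#' @export
#' @examples
#' edges <- tibble::tibble(symbol_a = c("A", "X"), symbol_b = c("X", "B"))
#' net <- build_subnetwork(edges, c("A", "B"))
#' tidy(net)
build_subnetwork <- function(edges, signature_genes, max_path_length = 2,
                             aliases = default_gene_aliases()) {
  if (is.character(edges) && length(edges) == 1) edges <- read_edge_list(edges)
  if (length(signature_genes) == 0) abort("`signature_genes` must be non-empty.")
  sig <- unique(canon_symbols(signature_genes, aliases))
  ea <- canon_symbols(edges$symbol_a, aliases)
  eb <- canon_symbols(edges$symbol_b, aliases)
  keep <- ea != eb
  if (any(!keep)) inform(sprintf("dropped %d self-loop edge(s).", sum(!keep)))

  g <- igraph::graph_from_data_frame(
    data.frame(from = ea[keep], to = eb[keep]), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

  sig_present <- intersect(sig, igraph::V(g)$name)
  sig_absent <- setdiff(sig, sig_present)
  if (length(sig_absent)) {
    warn(sprintf("signature gene(s) absent from the edge list, kept isolated: %s",
                 paste(sig_absent, collapse = ", ")))
  }

  bridges <- character(0)
  if (length(sig_present) >= 2) {
    d <- igraph::distances(g, v = sig_present)  # signature x all nodes
    cand <- setdiff(colnames(d), sig)
    # shortest path through v between two distinct signature genes
    via <- vapply(cand, function(v) {
      dv <- sort(d[, v])[1:2]
      sum(dv)
    }, numeric(1))
    bridges <- cand[is.finite(via) & via <= max_path_length]
  }

  nodes <- union(sig_present, bridges)
  sub <- igraph::induced_subgraph(g, nodes)
  sub <- igraph::add_vertices(sub, length(sig_absent), name = sig_absent)

  comp <- igraph::components(sub)
  node_tbl <- tibble(
    symbol = igraph::V(sub)$name,
    role = ifelse(igraph::V(sub)$name %in% sig, "signature", "bridge"),
    degree = unname(igraph::degree(sub)),
    component = unname(comp$membership[igraph::V(sub)$name])
  ) %>% arrange(.data$component, desc(.data$role == "signature"), .data$symbol)

  el <- igraph::as_edgelist(sub)
  edge_tbl <- tibble(symbol_a = pmin(el[, 1], el[, 2]),
                     symbol_b = pmax(el[, 1], el[, 2])) %>%
    arrange(.data$symbol_a, .data$symbol_b)

  structure(
    list(nodes = node_tbl, edges = edge_tbl, graph = sub,
         signature_genes = sig, max_path_length = max_path_length),
    class = "ppi_subnetwork"
  )
}

#' @export
print.ppi_subnetwork <- function(x, ...) {
  cat(sprintf("<ppi_subnetwork> %d nodes (%d signature, %d bridge), %d edges, %d component(s)\n",
              nrow(x$nodes), sum(x$nodes$role == "signature"),
              sum(x$nodes$role == "bridge"), nrow(x$edges),
              length(unique(x$nodes$component))))
  invisible(x)
}

#' @export
tidy.ppi_subnetwork <- function(x, ...) x$nodes

#' @export
glance.ppi_subnetwork <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_signature = sum(x$nodes$role == "signature"),
    n_bridge = sum(x$nodes$role == "bridge"),
    n_edges = nrow(x$edges),
    n_components = length(unique(x$nodes$component))
  )
}

#' Summarise the connected components of a subnetwork
#'
#' Components are ordered by decreasing size, ties broken by the
#' lexicographically smallest member, and renumbered in that order.
#'
#' @param net A [build_subnetwork()] result.
#' @return Tibble: `component`, `size`, `n_signature`, `members`
#'   (comma-separated, sorted symbols).
#' @export
component_summary <- function(net) {
  if (nrow(net$nodes) == 0) {
    return(tibble(component = integer(0), size = integer(0),
                  n_signature = integer(0), members = character(0)))
  }
  net$nodes %>%
    group_by(.data$component) %>%
    summarise(size = n(),
              n_signature = sum(.data$role == "signature"),
              members = paste(sort(.data$symbol), collapse = ","),
              .groups = "drop") %>%
    arrange(desc(.data$size), .data$members) %>%
    mutate(component = row_number()) %>%
    select("component", "size", "n_signature", "members")
}
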