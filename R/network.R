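# Protein-protein interaction networks over differentially expressed genes:
# assembly from an edge table with a confidence cutoff, node annotation, and
# small-component pruning.

#' Build an interaction network over differentially expressed genes
#'
#' Undirected graph whose nodes are the supplied genes (annotated with their
#' log2 fold change and up/down direction) and whose edges are the gene pairs
#' with interaction score at or above `min_score`. Edges referencing genes
#' not in `nodes` are ignored and logged.
#'
#' @param nodes Tibble `gene, log2fc` (e.g. the kept rows of
#'   [nanostring_de()] output, with `gene` and `log2fc` columns).
#' @param edges Tibble `gene_a, gene_b, score` with scores in `[0, 1]` and no
#'   self-interactions (self-edges are dropped with a warning).
#' @param min_score Minimum interaction confidence (default 0.4, the common
#'   medium-confidence convention).
#' @return An `igraph` graph with vertex attributes `log2fc` and `direction`;
#'   skipped edges are attached as the `"skipped_edges"` attribute.
#' @export
ppi_network <- function(nodes, edges, min_score = 0.4) {
  assert_cols(nodes, c("gene", "log2fc"), "`nodes`")
  assert_cols(edges, c("gene_a", "gene_b", "score"), "`edges`")
  if (nrow(edges) && (any(edges$score < 0) || any(edges$score > 1))) {
    abort("interaction scores must lie in [0, 1]")
  }
  if (any(duplicated(nodes$gene))) abort("duplicate genes in `nodes`")
  self <- edges$gene_a == edges$gene_b
  if (any(self)) {
    warn(sprintf("dropping %d self-edge(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  known <- edges$gene_a %in% nodes$gene & edges$gene_b %in% nodes$gene
  skipped <- edges[!known, , drop = FALSE]
  edges <- edges[known & edges$score >= min_score, , drop = FALSE]
  vertices <- nodes |>
    dplyr::transmute(name = .data$gene, log2fc = .data$log2fc,
                     direction = ifelse(.data$log2fc >= 0, "up", "down"))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "score")], directed = FALSE,
    vertices = vertices)
  attr(g, "skipped_edges") <- skipped
  g
}

#' Remove small isolated sub-networks
#'
#' Connected components with fewer than `min_size` genes (by default,
#' isolated sub-networks of 4 or fewer genes) are removed; components of
#' `min_size` or more are retained intact. Pruning is idempotent.
#'
#' @param graph An `igraph` graph.
#' @param min_size Smallest retained component size (default 5).
#' @return The pruned graph.
#' @export
prune_components <- function(graph, min_size = 5) {
  comp <- igraph::components(graph)
  keep <- which(comp$csize[comp$membership] >= min_size)
  igraph::induced_subgraph(graph, keep)
}

#' Export a network as node and edge tables
#'
#' @param graph An `igraph` graph from [ppi_network()].
#' @return List of tibbles `nodes` (gene, log2fc, direction) and `edges`
#'   (gene_a, gene_b, score).
#' @export
network_tables <- function(graph) {
  nodes <- tibble(
    gene = igraph::V(graph)$name,
    log2fc = igraph::V(graph)$log2fc,
    direction = igraph::V(graph)$direction)
  el <- igraph::as_edgelist(graph)
  edges <- tibble(gene_a = el[, 1], gene_b = el[, 2],
                  score = igraph::E(graph)$score %||% rep(NA_real_, nrow(el)))
  list(nodes = nodes, edges = edges)
}

#' Write a network to GraphML
#'
#' @param graph An `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
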