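#' Consensus miRNA-target selection
#'
#' Applies the consensus rule to a target-prediction table: a gene is kept
#' when at least two of the three prediction algorithms (TaPmiR, TargetScan,
#' miRDB) call it, or when it carries experimental validation. TaPmiR counts
#' toward the consensus only when its binding probability strictly exceeds
#' `tapmir_threshold`.
#'
#' @param predictions A tibble with one row per gene: `gene_symbol`,
#'   logical columns `tapmir`, `targetscan`, `mirdb`, optional numeric
#'   `tapmir_probability` (required where `tapmir` is `TRUE`), and logical
#'   `validated`.
#' @param tapmir_threshold Strict lower bound on the TaPmiR binding
#'   probability (default 0.95).
#' @param keep_all If `TRUE`, return every gene with a `selected` column;
#'   otherwise (default) only the selected genes.
#'
#' @return A tibble with `gene_symbol`, `n_algorithms` (qualifying
#'   algorithms), `validated` and, if `keep_all`, `selected`.
#' @export
consensus_targets <- function(predictions, tapmir_threshold = 0.95,
                              keep_all = FALSE) {
  needed <- c("gene_symbol", "tapmir", "targetscan", "mirdb", "validated")
  missing <- setdiff(needed, names(predictions))
  if (length(missing) > 0) {
    abort(paste0(
      "prediction table lacks column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(predictions$gene_symbol)) {
    abort("gene symbols must be unique in the prediction table")
  }
  prob <- predictions$tapmir_probability %||% rep(NA_real_, nrow(predictions))
  if (any(predictions$tapmir & is.na(prob))) {
    abort("tapmir_probability is required for every TaPmiR-predicted gene")
  }
  tapmir_ok <- predictions$tapmir & !is.na(prob) & prob > tapmir_threshold
  out <- predictions |>
    mutate(
      n_algorithms = tapmir_ok + .data$targetscan + .data$mirdb,
      selected = .data$n_algorithms >= 2 | .data$validated
    ) |>
    select("gene_symbol", "n_algorithms", "validated", "selected")
  if (keep_all) out else select(filter(out, .data$selected), -"selected")
}

#' Read an undirected edge list into a graph
#'
#' Parses a two-column whitespace- or tab-delimited edge list into a simple
#' undirected graph: duplicate edges are collapsed, self-loops are rejected
#' with a warning, and isolated nodes can be added via `nodes` so degree
#' statistics cover the whole target set.
#'
#' @param file Path to the edge list (two gene symbols per row; a third
#'   confidence column is tolerated and ignored).
#' @param nodes Optional character vector of node names to include even if
#'   they appear in no edge.
#'
#' @return An [igraph::graph] object (simple, undirected).
#' @export
read_edge_list <- function(file, nodes = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    parts <- strsplit(trimws(lines), "[ \t]+")
    short <- vapply(parts, length, integer(1)) < 2
    if (any(short)) abort("every edge row needs two node names")
    edges <- t(vapply(parts, function(p) p[1:2], character(2)))
  }
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warn(paste0("read_edge_list: dropped ", sum(loops), " self-loop row(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (!is.null(nodes)) {
    extra <- setdiff(nodes, igraph::V(g)$name)
    if (length(extra) > 0) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g
}

#' Build a graph from an edge table
#'
#' Convenience wrapper for edges already in a data frame (columns
#' `from`, `to`); same simplification rules as [read_edge_list()].
#'
#' @param edges Data frame with `from` and `to` character columns.
#' @inheritParams read_edge_list
#' @return An undirected simple [igraph::graph].
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(paste0("graph_from_edges: dropped ", sum(loops), " self-loop(s)"))
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::simplify(igraph::graph_from_data_frame(
    edges[c("from", "to")],
    directed = FALSE
  ))
  if (!is.null(nodes)) {
    extra <- setdiff(nodes, igraph::V(g)$name)
    if (length(extra) > 0) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g
}

#' Descriptive degree statistics of an interaction graph
#'
#' Node/edge counts, average node degree (`2 * edges / nodes`, the
#' whole-target-set convention: isolated nodes count in the denominator),
#' maximum degree and the highest-degree nodes.
#'
#' @param graph An undirected [igraph::graph] (e.g. from
#'   [read_edge_list()]).
#' @param top_n How many top-degree nodes to report (default 3).
#'
#' @return A one-row tibble: `n_nodes`, `n_edges`, `avg_degree`,
#'   `max_degree`, plus a list-column `top_nodes` holding a tibble of the
#'   `top_n` highest-degree nodes (`node`, `degree`), ties broken by name.
#' @export
degree_stats <- function(graph, top_n = 3) {
  n_nodes <- igraph::vcount(graph)
  if (n_nodes == 0) abort("graph has no nodes")
  n_edges <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  names(deg) <- igraph::V(graph)$name %||% as.character(seq_len(n_nodes))
  ord <- order(-deg, names(deg))
  top <- tibble(
    node = names(deg)[ord][seq_len(min(top_n, n_nodes))],
    degree = unname(deg[ord][seq_len(min(top_n, n_nodes))])
  )
  tibble(
    n_nodes = n_nodes,
    n_edges = n_edges,
    avg_degree = 2 * n_edges / n_nodes,
    max_degree = max(deg),
    top_nodes = list(top)
  )
}
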