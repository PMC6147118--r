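#' Convert a quantitative network to an undirected bipartite graph
#'
#' One vertex per node on either side, an edge wherever `a_ij > 0`.
#' Centrality is computed on this binary graph; interaction weights can be
#' attached as an edge attribute but the standard metrics ignore them.
#'
#' @param net a [quant_network()] or count matrix.
#' @param weighted attach `weight` edge attributes.
#' @return an `igraph` graph with vertex attributes `name`, `side` and the
#'   logical `type` (TRUE for bees) used by bipartite layouts.
#' @export
as_bipartite_graph <- function(net, weighted = FALSE) {
  m <- as_qmatrix(net)
  rn <- rownames(m); cn <- colnames(m)
  if (any(rn %in% cn)) {       # species label shared across sides
    rn <- paste0("plant:", rn); cn <- paste0("bee:", cn)
    dimnames(m) <- list(rn, cn)
  }
  g <- igraph::graph_from_biadjacency_matrix(m > 0)
  igraph::V(g)$side <- ifelse(igraph::V(g)$type, "bee", "plant")
  if (weighted) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- m[cbind(match(el[, 1], rn), match(el[, 2], cn))]
  }
  g
}

#' Normalized degree centrality
#'
#' The fraction of potential partners a node actually interacts with:
#' for bee `j` the number of plant nodes with `a_ij > 0` divided by `P`,
#' and symmetrically for plants.  Binary by definition, so invariant to
#' the interaction weights.
#'
#' @param net a [quant_network()] or count matrix.
#' @return list with named vectors `plant` and `bee`, values in `[0, 1]`.
#' @export
normalized_degree <- function(net) {
  m <- as_qmatrix(net)
  list(plant = rowSums(m > 0) / ncol(m),
       bee = colSums(m > 0) / nrow(m))
}

#' Closeness centrality on the bipartite graph
#'
#' Unweighted shortest-path closeness with component-size scaling for
#' disconnected graphs: a vertex in a component of size `c` within a graph
#' of `N` vertices scores `((c - 1) / sum of distances) * ((c - 1) /
#' (N - 1))`, which reduces to the classical normalized closeness when the
#' graph is connected and penalizes small components.  Isolated vertices
#' score 0.
#'
#' @param graph an igraph graph (see [as_bipartite_graph()]).
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(graph) {
  D <- igraph::distances(graph)
  N <- nrow(D)
  vapply(seq_len(N), function(v) {
    d <- D[v, -v]
    fin <- d[is.finite(d)]
    cs <- length(fin) + 1          # component size
    if (cs == 1 || sum(fin) == 0) return(0)
    ((cs - 1) / sum(fin)) * ((cs - 1) / (N - 1))
  }, numeric(1)) |> stats::setNames(rownames(D))
}

#' Betweenness centrality on the bipartite graph
#'
#' Shortest-path betweenness over all vertex pairs (both sides in one
#' vertex set), normalized by `(N - 1)(N - 2) / 2`.
#'
#' @param graph an igraph graph.
#' @return named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(graph) {
  b <- igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
  stats::setNames(as.numeric(b), igraph::V(graph)$name)
}

#' Full centrality report for a network
#'
#' @param net a [quant_network()] or count matrix.
#' @return a data.frame of class `centrality_report`: `node`, `side`,
#'   `normalized_degree`, `closeness`, `betweenness`, `component`, and
#'   per-metric ranks (`rank_nd`, `rank_cl`, `rank_bt`; descending, ties
#'   share the best rank).
#' @export
node_centrality <- function(net) {
  m <- as_qmatrix(net)
  g <- as_bipartite_graph(net)
  nd <- normalized_degree(net)
  cl <- closeness_centrality(g)
  bt <- betweenness_centrality(g)
  comp <- igraph::components(g)$membership
  df <- data.frame(
    node = c(rownames(m), colnames(m)),
    side = c(rep("plant", nrow(m)), rep("bee", ncol(m))),
    normalized_degree = c(nd$plant, nd$bee),
    closeness = as.numeric(cl),
    betweenness = as.numeric(bt),
    component = as.integer(comp),
    stringsAsFactors = FALSE
  )
  df$rank_nd <- rank(-df$normalized_degree, ties.method = "min")
  df$rank_cl <- rank(-df$closeness, ties.method = "min")
  df$rank_bt <- rank(-df$betweenness, ties.method = "min")
  class(df) <- c("centrality_report", "data.frame")
  df
}

#' Rank nodes by a centrality metric
#'
#' @param report a `centrality_report`.
#' @param metric one of `"normalized_degree"`, `"closeness"`,
#'   `"betweenness"`.
#' @param side restrict to `"plant"` or `"bee"` nodes (default: both).
#' @return the report rows in stable descending order of the metric, with
#'   a `rank` column (ties share the best rank).
#' @export
most_central <- function(report,
                         metric = c("normalized_degree", "closeness",
                                    "betweenness"),
                         side = NULL) {
  metric <- match.arg(metric)
  df <- as.data.frame(report)
  if (!is.null(side)) df <- df[df$side == side, ]
  df <- df[order(-df[[metric]]), ]
  df$rank <- rank(-df[[metric]], ties.method = "min")
  rownames(df) <- NULL
  df
}
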