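#' Construct a quantitative bipartite network
#'
#' A quantitative bipartite network is a non-negative count matrix with
#' plant nodes as rows and bee nodes as columns; cell `a_ij` is the number
#' of observed visits between plant node `i` and bee node `j`.  No row or
#' column may be all zero, and row/column labels must be unique.
#'
#' @param matrix numeric matrix of non-negative counts with dimnames.
#' @param plant_meta,bee_meta optional data.frames of node metadata, one
#'   row per node in matrix order.
#' @return a list of class `quant_network`: `matrix`, `plant_meta`,
#'   `bee_meta`, `m` (total interactions).
#' @export
quant_network <- function(matrix, plant_meta = NULL, bee_meta = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (length(m) == 0) stop("empty matrix")
  if (any(!is.finite(m)) || any(m < 0)) stop("counts must be finite and >= 0")
  if (is.null(rownames(m))) rownames(m) <- sprintf("F%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("B%02d", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("node labels must be unique")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("network has an all-zero row or column")
  }
  structure(list(matrix = m, plant_meta = plant_meta, bee_meta = bee_meta,
                 m = sum(m)),
            class = "quant_network")
}

#' @export
print.quant_network <- function(x, ...) {
  cat(sprintf("quantitative bipartite network: %d plant x %d bee nodes, %g interactions\n",
              nrow(x$matrix), ncol(x$matrix), x$m))
  invisible(x)
}

#' @export
as.matrix.quant_network <- function(x, ...) x$matrix

#' @export
dim.quant_network <- function(x) dim(x$matrix)

# shared aggregator: counts records into a plant-node x bee-node matrix,
# ordering nodes by ascending mean member trait (ties by label)
aggregate_bipartite <- function(plant_node, bee_node, plant_trait,
                                bee_trait) {
  stopifnot(length(plant_node) == length(bee_node))
  tab <- table(plant_node, bee_node)
  mat <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  pmean <- tapply(plant_trait, plant_node, mean)[rownames(mat)]
  bmean <- tapply(bee_trait, bee_node, mean)[colnames(mat)]
  mat <- mat[order(pmean, rownames(mat)), order(bmean, colnames(mat)),
             drop = FALSE]
  pm <- data.frame(node = rownames(mat),
                   trait_mean = as.numeric(sort_by_match(pmean, rownames(mat))),
                   n_records = as.numeric(rowSums(mat)),
                   stringsAsFactors = FALSE)
  bm <- data.frame(node = colnames(mat),
                   trait_mean = as.numeric(sort_by_match(bmean, colnames(mat))),
                   n_records = as.numeric(colSums(mat)),
                   stringsAsFactors = FALSE)
  quant_network(mat, plant_meta = pm, bee_meta = bm)
}

sort_by_match <- function(v, labels) v[match(labels, names(v))]

#' Build the species-based network
#'
#' Nodes are plant and bee species; `a_ij` counts the records pairing
#' plant species `i` with bee species `j`.  Nodes are sorted from the
#' smallest to the largest mean functional size of their member records
#' (predicted nectar holder depth for plants when available, floral
#' display size otherwise; intertegular distance for bees).
#'
#' @param records an `interaction_records` data.frame (optionally with the
#'   `nhd_mm` column from [predict_functional_traits()]).
#' @return a [quant_network()].
#' @export
build_species_network <- function(records) {
  if (nrow(records) == 0) stop("no interaction records")
  plant_trait <- records$nhd_mm %||% records$fds_mm
  aggregate_bipartite(records$plant_species, records$bee_species,
                      plant_trait, records$itd_mm)
}

#' Build the trait-based network
#'
#' Nodes are functional-size clusters; `a_ij` counts the records whose
#' flower falls in plant node `i` and whose bee falls in bee node `j`.
#' The total number of interactions is preserved exactly.
#'
#' @param records an `interaction_records` data.frame.
#' @param plant_clusters,bee_clusters `trait_clusters` objects whose
#'   assignments are named by `record_id` (each record contributes one
#'   flower individual and one bee individual).
#' @return a [quant_network()]; its node metadata carries the cluster
#'   trait ranges and species counts.
#' @export
build_trait_network <- function(records, plant_clusters, bee_clusters) {
  if (nrow(records) == 0) stop("no interaction records")
  pn <- plant_clusters$assignment[records$record_id]
  bn <- bee_clusters$assignment[records$record_id]
  if (anyNA(pn) || anyNA(bn)) {
    missing <- records$record_id[is.na(pn) | is.na(bn)]
    stop("record(s) not assigned to a cluster: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  plant_trait <- records$nhd_mm %||% records$fds_mm
  net <- aggregate_bipartite(pn, bn, plant_trait, records$itd_mm)
  net$plant_meta <- merge_cluster_meta(net$plant_meta, plant_clusters)
  net$bee_meta <- merge_cluster_meta(net$bee_meta, bee_clusters)
  net
}

merge_cluster_meta <- function(meta, clusters) {
  nd <- clusters$nodes
  idx <- match(meta$node, nd$node_id)
  meta$trait_min <- nd$trait_min[idx]
  meta$trait_max <- nd$trait_max[idx]
  if (!is.null(nd$n_species)) meta$n_species <- nd$n_species[idx]
  meta
}
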