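#' Pairwise 1-D Euclidean distances between trait values
#'
#' @param values numeric vector of trait values (mm).
#' @return a symmetric matrix of absolute differences with zero diagonal.
#' @export
trait_dist <- function(values) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("trait values must be finite")
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(names(values), names(values))
  d
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Clusters individuals by a single functional size trait using average
#' linkage on 1-D Euclidean distances: at every step the pair of clusters
#' with the smallest mean pairwise inter-cluster distance is merged.
#' Ties (which occur whenever trait values repeat) are broken
#' deterministically towards the pair whose members carry the lowest
#' original indices, so identical inputs always produce identical trees.
#'
#' The result is encoded as a standard [stats::hclust] object
#' (`method = "average"`), so [stats::cutree()], [stats::cophenetic()] and
#' plotting all work.
#'
#' @param values numeric vector of trait values (mm), optionally named with
#'   individual ids.
#' @param labels leaf labels; defaults to `names(values)` or indices.
#' @return an object of class `hclust`.
#' @export
upgma <- function(values, labels = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2) stop("need at least 2 individuals")
  if (any(!is.finite(x))) stop("trait values must be finite")
  labels <- labels %||% names(values) %||% as.character(seq_len(n))

  D <- abs(outer(x, x, "-"))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minmem <- seq_len(n)          # lowest original leaf index in each slot
  node <- -seq_len(n)           # hclust encoding: negative leaf, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: smallest (min original index, then other min index)
    a <- idx[cand[, 1]]; b <- idx[cand[, 2]]
    lo <- pmin(minmem[a], minmem[b]); hi <- pmax(minmem[a], minmem[b])
    pick <- order(lo, hi)[1]
    i <- a[pick]; j <- b[pick]
    if (minmem[j] < minmem[i]) { tmp <- i; i <- j; j <- tmp }

    pair <- sort(c(node[i], node[j]))
    merge[s, ] <- if (pair[1] < 0 && pair[2] < 0) rev(pair) else pair
    height[s] <- if (s > 1) max(dmin, height[s - 1]) else dmin

    # Lance-Williams update for average linkage
    others <- idx[idx != i & idx != j]
    if (length(others)) {
      dnew <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- dnew
      D[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    node[i] <- s
    D[j, ] <- Inf; D[, j] <- Inf
  }

  structure(list(merge = merge, height = height,
                 order = hclust_order(merge),
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

# left-to-right leaf ordering from an hclust merge matrix (iterative)
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  stack <- list(nrow(merge))
  out <- integer(0)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top < 0) {
      out <- c(out, -top)
    } else {
      stack <- c(stack, list(merge[top, 2], merge[top, 1]))
    }
  }
  out
}

#' Cut a dendrogram into k functional-size nodes
#'
#' Cuts the tree into `k` clusters and packages them as size nodes:
#' node ids run from the smallest to the largest mean trait
#' (`B01...Bk` for bees, `F01...Fk` for flowers), and each node carries its
#' trait range and species composition.  Because the trait is
#' one-dimensional and the linkage is average, node trait ranges never
#' interleave.
#'
#' @param tree an `hclust` tree from [upgma()].
#' @param k number of clusters, `1 <= k <= n`.
#' @param values the trait values the tree was built from (same order).
#' @param species character vector of species labels per individual.
#' @param side `"bee"` or `"plant"` (controls the `B`/`F` node prefix).
#' @return a list of class `trait_clusters`: `side`, `k`, `assignment`
#'   (named character vector: individual id -> node id), `nodes`
#'   (data.frame `node_id`, `n`, `trait_min`, `trait_max`, `trait_mean`),
#'   `composition` (named list of species count tables).
#' @export
cut_clusters <- function(tree, k, values, species = NULL,
                         side = c("bee", "plant")) {
  side <- match.arg(side)
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  if (length(values) != n) stop("values length must match tree leaves")
  raw <- stats::cutree(tree, k = k)
  means <- tapply(as.numeric(values), factor(raw, levels = seq_len(k)), mean)
  remap <- order(means)                      # cluster index by ascending mean
  new_id <- match(raw, remap)                # 1 = smallest mean trait
  prefix <- if (side == "bee") "B" else "F"
  node_ids <- sprintf("%s%02d", prefix, seq_len(k))
  assignment <- stats::setNames(node_ids[new_id], tree$labels)

  nodes <- data.frame(
    node_id = node_ids,
    n = as.integer(tabulate(new_id, k)),
    trait_min = vapply(seq_len(k), function(g) min(values[new_id == g]), 0),
    trait_max = vapply(seq_len(k), function(g) max(values[new_id == g]), 0),
    trait_mean = vapply(seq_len(k), function(g) mean(values[new_id == g]), 0),
    stringsAsFactors = FALSE
  )
  composition <- NULL
  if (!is.null(species)) {
    composition <- lapply(seq_len(k), function(g) table(species[new_id == g]))
    names(composition) <- node_ids
    nodes$n_species <- vapply(composition, length, integer(1))
  }
  structure(list(side = side, k = k, assignment = assignment,
                 nodes = nodes, composition = composition),
            class = "trait_clusters")
}

#' @export
print.trait_clusters <- function(x, ...) {
  cat(sprintf("%d %s size nodes (%d individuals)\n", x$k, x$side,
              length(x$assignment)))
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Choose the number of clusters by a cluster-validity index vote
#'
#' Cuts the average-linkage tree at every `k` in `k_range` and scores each
#' partition with five classical validity indices: silhouette width
#' (maximize), Calinski-Harabasz (maximize), Davies-Bouldin (minimize),
#' Dunn (maximize) and C-index (minimize).  Each index votes for its best
#' `k`; the majority wins and ties go to the smallest `k` (parsimony).
#'
#' @param values numeric trait vector, `n >= 4`.
#' @param k_range candidate cluster counts; default `2:min(15, n - 1)`.
#' @return list `k_best`, `votes` (named integer vector), `scores`
#'   (data.frame of index values per k).
#' @export
optimal_k <- function(values, k_range = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 4) stop("need at least 4 individuals to choose k")
  k_range <- k_range %||% 2:min(15, n - 1)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty k_range")
  tree <- upgma(x)
  D <- abs(outer(x, x, "-"))
  scores <- t(vapply(k_range, function(k) {
    cl <- stats::cutree(tree, k = k)
    cluster_indices(x, cl, D)
  }, numeric(5)))
  scores <- as.data.frame(scores)
  names(scores) <- c("silhouette", "ch", "db", "dunn", "cindex")
  scores$k <- k_range

  best_of <- function(v, maximize) {
    v[!is.finite(v)] <- if (maximize) -Inf else Inf
    k_range[if (maximize) which.max(v) else which.min(v)]
  }
  votes_for <- c(silhouette = best_of(scores$silhouette, TRUE),
                 ch = best_of(scores$ch, TRUE),
                 db = best_of(scores$db, FALSE),
                 dunn = best_of(scores$dunn, TRUE),
                 cindex = best_of(scores$cindex, FALSE))
  tab <- table(votes_for)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k_best = min(winners), votes = votes_for, scores = scores)
}

# the five validity indices for one 1-D partition; D = full distance matrix
cluster_indices <- function(x, cl, D) {
  n <- length(x)
  k <- length(unique(cl))
  sizes <- tabulate(cl, k)
  cent <- tapply(x, cl, mean)

  # silhouette (singleton clusters score 0, the usual convention)
  sil <- vapply(seq_len(n), function(i) {
    own <- cl[i]
    if (sizes[own] == 1) return(0)
    a <- sum(D[i, cl == own]) / (sizes[own] - 1)
    b <- min(vapply(setdiff(seq_len(k), own), function(g) {
      mean(D[i, cl == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  gm <- mean(x)
  ssb <- sum(sizes * (cent - gm)^2)
  ssw <- sum((x - cent[cl])^2)
  ch <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))

  s_i <- vapply(seq_len(k), function(g) mean(abs(x[cl == g] - cent[g])),
                numeric(1))
  db <- mean(vapply(seq_len(k), function(g) {
    r <- vapply(setdiff(seq_len(k), g), function(h) {
      dd <- abs(cent[g] - cent[h])
      if (dd == 0) Inf else (s_i[g] + s_i[h]) / dd
    }, numeric(1))
    max(r)
  }, numeric(1)))

  diam <- max(vapply(seq_len(k), function(g) {
    if (sizes[g] == 1) 0 else max(D[cl == g, cl == g])
  }, numeric(1)))
  sep <- min(vapply(seq_len(k - 1), function(g) {
    min(vapply((g + 1):k, function(h) min(D[cl == g, cl == h, drop = FALSE]),
               numeric(1)))
  }, numeric(1)))
  dunn <- if (diam == 0) Inf else sep / diam

  within <- outer(cl, cl, "==") & upper.tri(D)
  s_w <- sum(D[within])
  n_w <- sum(within)
  all_d <- sort(D[upper.tri(D)])
  s_min <- sum(all_d[seq_len(n_w)])
  s_max <- sum(all_d[seq.int(length(all_d) - n_w + 1L, length(all_d))])
  cindex <- if (s_max == s_min) 0 else (s_w - s_min) / (s_max - s_min)

  c(mean(sil), ch, db, dunn, cindex)
}

#' Export cluster assignments and node summaries
#'
#' @param clusters a `trait_clusters` object.
#' @param csv_path optional path for the `individual_id, node_id` CSV.
#' @param json_path optional path for the JSON node summary.
#' @return the node summary list, invisibly.
#' @export
write_clusters <- function(clusters, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(individual_id = names(clusters$assignment),
                                node_id = unname(clusters$assignment)),
                     csv_path, row.names = FALSE)
  }
  summ <- lapply(seq_len(clusters$k), function(g) {
    nd <- clusters$nodes[g, ]
    comp <- clusters$composition[[nd$node_id]]
    list(node = nd$node_id, k = clusters$k, trait_min = nd$trait_min,
         trait_max = nd$trait_max,
         species = if (!is.null(comp)) as.list(comp) else NULL)
  })
  if (!is.null(json_path)) {
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
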