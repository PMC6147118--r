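#' Weighted (quantitative) connectance
#'
#' Entropy-based connectance for count matrices: every node `t` with total
#' `T_t` and interaction proportions `p` has `n_t = 2^(H_t)` effective
#' partners, where `H_t = -sum(p * log2(p))` is its Shannon entropy.  The
#' quantitative linkage density is
#' `LDq = (1/(2m)) * (sum_j B_j n_j + sum_i A_i n_i)` (marginal-weighted
#' mean effective partner number) and `Cq = LDq / (P + A)`.
#'
#' @param net a [quant_network()] or count matrix.
#' @return `Cq`, a number in `(0, 1]`.
#' @export
weighted_connectance <- function(net) {
  m <- as_qmatrix(net)
  tot <- sum(m)
  if (tot <= 0) stop("empty matrix")
  eff <- function(v) {
    p <- v[v > 0] / sum(v)
    2^(-sum(p * log2(p)))
  }
  n_row <- apply(m, 1, eff)
  n_col <- apply(m, 2, eff)
  ldq <- (sum(colSums(m) * n_col) + sum(rowSums(m) * n_row)) / (2 * tot)
  ldq / (nrow(m) + ncol(m))
}

#' Weighted nestedness (WNODF)
#'
#' Weighted NODF on the count matrix: rows and columns are first ordered
#' by decreasing marginal totals (stable sort, ties keep the original
#' order).  For an ordered pair (`u` above `v`) with strictly larger total,
#' the pair score is `100 * #{cells c: 0 < x_vc < x_uc} / #{cells c:
#' x_vc > 0}`; pairs with equal or increasing totals score 0.  WNODF is
#' the mean over all row pairs and all column pairs, from 0 (not nested)
#' to 100 (fully nested).
#'
#' @param net a [quant_network()] or count matrix, at least 2x2.
#' @return WNODF in `[0, 100]`.
#' @export
wnodf <- function(net) {
  m <- as_qmatrix(net)
  if (nrow(m) < 2 || ncol(m) < 2) stop("WNODF needs at least a 2x2 matrix")
  m <- m[order(rowSums(m), decreasing = TRUE), , drop = FALSE]
  m <- m[, order(colSums(m), decreasing = TRUE), drop = FALSE]
  mean(c(wnodf_pairs(m), wnodf_pairs(t(m))))
}

# scores for all ordered row pairs of a margin-sorted matrix
wnodf_pairs <- function(m) {
  n <- nrow(m)
  tot <- rowSums(m)
  scores <- numeric(n * (n - 1) / 2)
  s <- 0L
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      s <- s + 1L
      if (tot[u] <= tot[v]) next         # decreasing fill violated -> 0
      nz <- m[v, ] > 0
      if (!any(nz)) next
      scores[s] <- 100 * sum(m[v, nz] < m[u, nz]) / sum(nz)
    }
  }
  scores
}

#' Interaction evenness
#'
#' Shannon evenness of the interaction frequencies:
#' `IE = H / log(P * A)` with `H = -sum(p_ij * log(p_ij))` over non-zero
#' cells and `p_ij = a_ij / m`.  With `denominator = "realized_links"` the
#' divisor is `log(number of non-zero cells)` instead.
#'
#' @param net a [quant_network()] or count matrix.
#' @param denominator `"all_cells"` (default) or `"realized_links"`.
#' @return IE in `[0, 1]`.
#' @export
interaction_evenness <- function(net,
                                 denominator = c("all_cells",
                                                 "realized_links")) {
  denominator <- match.arg(denominator)
  m <- as_qmatrix(net)
  tot <- sum(m)
  if (tot <= 0) stop("empty matrix")
  p <- m[m > 0] / tot
  H <- -sum(p * log(p))
  denom <- if (denominator == "all_cells") log(nrow(m) * ncol(m))
           else log(sum(m > 0))
  if (denom <= 0) return(0)
  H / denom
}

#' Network-level complementary specialization H2'
#'
#' Two-dimensional Shannon entropy of the interaction matrix, standardized
#' between the extremes attainable under the observed marginal totals:
#' `H2' = (H2max - H2) / (H2max - H2min)` with
#' `H2 = -sum(p_ij log p_ij)`.  `H2max` is the entropy of the proportional
#' (independence) table `A_i B_j / m`; `H2min` comes from a greedy fill
#' that repeatedly allocates `min(remaining row, remaining column)` to the
#' largest remaining margins (maximally aggregated, hence minimal
#' entropy).  Values are clamped to `[0, 1]`; 0 means no specialization,
#' 1 complete specialization.
#'
#' @param net a [quant_network()] or count matrix.
#' @return H2' in `[0, 1]` (0 with attribute `degenerate = TRUE` when the
#'   extremes coincide, e.g. a 1x1 matrix).
#' @export
h2prime <- function(net) {
  m <- as_qmatrix(net)
  tot <- sum(m)
  if (tot <= 0) stop("empty matrix")
  p <- m[m > 0] / tot
  H2 <- -sum(p * log(p))
  ent <- function(v) { q <- v[v > 0] / sum(v); -sum(q * log(q)) }
  H2max <- ent(rowSums(m)) + ent(colSums(m))
  H2min <- greedy_min_entropy(rowSums(m), colSums(m))
  if (H2max - H2min < 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  min(1, max(0, (H2max - H2) / (H2max - H2min)))
}

# minimal-entropy table entropy under fixed margins (greedy heuristic)
greedy_min_entropy <- function(r, c) {
  tot <- sum(r)
  cells <- numeric(0)
  while (sum(r) > 1e-9) {
    i <- which.max(r); j <- which.max(c)
    a <- min(r[i], c[j])
    cells <- c(cells, a)
    r[i] <- r[i] - a; c[j] <- c[j] - a
  }
  p <- cells / tot
  -sum(p * log(p))
}

#' Node-level specialization d'
#'
#' Kullback-Leibler specialization of every node on one side: a node with
#' visit proportions `p'` against partner availability `q` (the partners'
#' share of all interactions) has raw divergence
#' `d = sum(p' * log(p'/q))`, standardized as `d' = (d - dmin) /
#' (dmax - dmin)`.  `dmax` is the divergence of the most specialized
#' integer-feasible allocation (fill partners from the rarest upward,
#' capped by their totals); `dmin` the divergence of the
#' largest-remainder rounding of the proportional allocation.  0 means the
#' node uses partners in proportion to availability, 1 maximal
#' specialization.
#'
#' @param net a [quant_network()] or count matrix.
#' @param side `"bee"` (columns) or `"plant"` (rows).
#' @return named numeric vector of d' in `[0, 1]`, one per node.
#' @export
d_prime <- function(net, side = c("bee", "plant")) {
  side <- match.arg(side)
  m <- as_qmatrix(net)
  if (side == "plant") m <- t(m)
  # now: columns are focal nodes, rows are partners
  part_tot <- rowSums(m)
  tot <- sum(m)
  if (any(part_tot == 0) || any(colSums(m) == 0)) {
    stop("d' needs a matrix without zero margins")
  }
  q <- part_tot / tot
  kl <- function(alloc) {
    pp <- alloc / sum(alloc)
    nz <- pp > 0
    sum(pp[nz] * log(pp[nz] / q[nz]))
  }
  vapply(seq_len(ncol(m)), function(j) {
    B <- sum(m[, j])
    d <- kl(m[, j])
    # most specialized feasible allocation: rarest partners first
    ord <- order(q)
    alloc_max <- numeric(length(q))
    rem <- B
    for (i in ord) {
      take <- min(rem, part_tot[i])
      alloc_max[i] <- take
      rem <- rem - take
      if (rem <= 0) break
    }
    dmax <- kl(alloc_max)
    # closest-to-proportional integer allocation (largest remainder)
    base <- floor(B * q)
    left <- round(B - sum(base))
    if (left > 0) {
      frac <- B * q - base
      base[order(frac, decreasing = TRUE)[seq_len(left)]] <-
        base[order(frac, decreasing = TRUE)[seq_len(left)]] + 1
    }
    dmin <- kl(base)
    if (dmax - dmin < 1e-12) return(0)
    min(1, max(0, (d - dmin) / (dmax - dmin)))
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(m))
}

#' Node strength (sum of partner dependencies)
#'
#' The dependency of plant `i` on bee `j` is `a_ij / A_i` (the bee's share
#' of the plant's visits); the strength of bee `j` is the sum of these
#' dependencies over plants.  Symmetrically for plants.  Strengths on one
#' side always sum to the number of nodes on the other side.
#'
#' @param net a [quant_network()] or count matrix with no zero margins.
#' @param side `"bee"` or `"plant"`.
#' @return named numeric vector of strengths (>= 0).
#' @export
node_strength <- function(net, side = c("bee", "plant")) {
  side <- match.arg(side)
  m <- as_qmatrix(net)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("strength needs a matrix without zero margins")
  }
  if (side == "bee") colSums(m / rowSums(m))
  else rowSums(sweep(m, 2, colSums(m), "/"))
}

#' Compute the full metric report for one network
#'
#' @param net a [quant_network()].
#' @param ie_denominator passed to [interaction_evenness()].
#' @return a list of class `metric_report`: `P`, `A`, `m`, `Cq`, `WNODF`
#'   (`NA` for matrices smaller than 2x2), `IE`, `H2prime`, per-node `d'`
#'   and strength vectors, and `summary` (mean and SD per side, as
#'   printed in comparison tables).
#' @export
network_metrics <- function(net, ie_denominator = "all_cells") {
  m <- as_qmatrix(net)
  msd <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  db <- d_prime(m, "bee"); dp <- d_prime(m, "plant")
  sb <- node_strength(m, "bee"); sp <- node_strength(m, "plant")
  structure(list(
    P = nrow(m), A = ncol(m), m = sum(m),
    Cq = weighted_connectance(m),
    WNODF = if (nrow(m) >= 2 && ncol(m) >= 2) wnodf(m) else NA_real_,
    IE = interaction_evenness(m, ie_denominator),
    H2prime = as.numeric(h2prime(m)),
    d_prime_bee = db, d_prime_plant = dp,
    strength_bee = sb, strength_plant = sp,
    summary = rbind(d_prime_bee = msd(db), d_prime_plant = msd(dp),
                    strength_bee = msd(sb), strength_plant = msd(sp))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("P = %d, A = %d, m = %g\n", x$P, x$A, x$m))
  cat(sprintf("Cq = %.*f  WNODF = %.*f  IE = %.*f  H2' = %.*f\n",
              digits, x$Cq, digits, x$WNODF, digits, x$IE, digits,
              x$H2prime))
  s <- x$summary
  for (r in rownames(s)) {
    cat(sprintf("%-15s %.*f +/- %.*f\n", r, digits, s[r, "mean"],
                digits, s[r, "sd"]))
  }
  invisible(x)
}
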