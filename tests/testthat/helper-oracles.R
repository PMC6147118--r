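# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (scalar loops, recomputation from scratch) so they
# share no code path with the package implementations they check.

# random count matrix with no zero row/column
random_count_matrix <- function(P, A, m = 4 * P * A) {
  repeat {
    v <- as.integer(rmultinom(1, m, rep(1 / (P * A), P * A)))
    mat <- matrix(v, P, A)
    if (all(rowSums(mat) > 0) && all(colSums(mat) > 0)) return(mat)
  }
}

# --- metrics ------------------------------------------------------------

oracle_strength <- function(mat, side) {
  if (side == "plant") mat <- t(mat)
  # focal nodes are columns of mat now
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    s <- 0
    for (i in seq_len(nrow(mat))) s <- s + mat[i, j] / sum(mat[i, ])
    out[j] <- s
  }
  out
}

oracle_cq <- function(mat) {
  eff <- function(v) {
    p <- v[v > 0] / sum(v)
    h <- 0
    for (q in p) h <- h - q * log2(q)
    2^h
  }
  tot <- sum(mat)
  acc <- 0
  for (i in seq_len(nrow(mat))) acc <- acc + sum(mat[i, ]) * eff(mat[i, ])
  for (j in seq_len(ncol(mat))) acc <- acc + sum(mat[, j]) * eff(mat[, j])
  (acc / (2 * tot)) / (nrow(mat) + ncol(mat))
}

oracle_wnodf <- function(mat) {
  mat <- mat[order(rowSums(mat), decreasing = TRUE), , drop = FALSE]
  mat <- mat[, order(colSums(mat), decreasing = TRUE), drop = FALSE]
  pair_scores <- function(m) {
    sc <- c()
    for (u in seq_len(nrow(m) - 1)) {
      for (v in (u + 1):nrow(m)) {
        if (sum(m[u, ]) <= sum(m[v, ])) { sc <- c(sc, 0); next }
        num <- 0; den <- 0
        for (cc in seq_len(ncol(m))) {
          if (m[v, cc] > 0) {
            den <- den + 1
            if (m[v, cc] < m[u, cc]) num <- num + 1
          }
        }
        sc <- c(sc, if (den == 0) 0 else 100 * num / den)
      }
    }
    sc
  }
  mean(c(pair_scores(mat), pair_scores(t(mat))))
}

oracle_ie <- function(mat) {
  tot <- sum(mat)
  h <- 0
  for (v in mat[mat > 0]) h <- h - (v / tot) * log(v / tot)
  h / log(nrow(mat) * ncol(mat))
}

oracle_h2 <- function(mat) {
  tot <- sum(mat)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h2 <- ent(as.vector(mat) / tot)
  h2max <- ent(rowSums(mat) / tot) + ent(colSums(mat) / tot)
  r <- rowSums(mat); cc <- colSums(mat)
  cells <- c()
  while (sum(r) > 0) {
    i <- which.max(r); j <- which.max(cc)
    a <- min(r[i], cc[j])
    cells <- c(cells, a)
    r[i] <- r[i] - a; cc[j] <- cc[j] - a
  }
  h2min <- ent(cells / tot)
  if (h2max - h2min < 1e-12) return(0)
  min(1, max(0, (h2max - h2) / (h2max - h2min)))
}

oracle_dprime <- function(mat, side) {
  if (side == "plant") mat <- t(mat)
  part <- rowSums(mat)
  q <- part / sum(mat)
  kl <- function(a) {
    p <- a / sum(a)
    s <- 0
    for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
    s
  }
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    B <- sum(mat[, j])
    amax <- numeric(length(q)); rem <- B
    for (i in order(q)) {
      take <- min(rem, part[i]); amax[i] <- take; rem <- rem - take
      if (rem == 0) break
    }
    base <- floor(B * q); left <- round(B - sum(base))
    if (left > 0) {
      ord <- order(B * q - base, decreasing = TRUE)
      base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    d <- kl(mat[, j]); dmax <- kl(amax); dmin <- kl(base)
    out[j] <- if (dmax - dmin < 1e-12) 0 else
      min(1, max(0, (d - dmin) / (dmax - dmin)))
  }
  out
}

# --- clustering ---------------------------------------------------------

# quadratic brute-force UPGMA: recompute all average inter-cluster
# distances from the raw values at every step; same tie-break rule as
# upgma() (lowest min original index, then the other cluster's min index).
# Returns merge heights and the cophenetic distance matrix.
oracle_upgma <- function(x) {
  n <- length(x)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- 0
        for (i in clusters[[a]]) for (j in clusters[[b]]) {
          d <- d + abs(x[i] - x[j])
        }
        d <- d / (length(clusters[[a]]) * length(clusters[[b]]))
        key <- c(d, min(min(clusters[[a]]), min(clusters[[b]])),
                 max(min(clusters[[a]]), min(clusters[[b]])))
        if (is.null(best) ||
            d < best$key[1] - 1e-12 ||
            (abs(d - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    heights[s] <- best$key[1]
    for (i in clusters[[best$a]]) for (j in clusters[[best$b]]) {
      coph[i, j] <- coph[j, i] <- best$key[1]
    }
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# --- centrality ---------------------------------------------------------

# all-pairs shortest-path betweenness by explicit path enumeration (DFS
# over BFS distance levels), normalized by (N-1)(N-2)/2
oracle_betweenness <- function(adj) {
  N <- nrow(adj)
  bt <- numeric(N)
  dist_from <- function(s) {
    d <- rep(Inf, N); d[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) {
        if (d[w] == Inf) { d[w] <- d[v] + 1; queue <- c(queue, w) }
      }
    }
    d
  }
  all_shortest_paths <- function(s, t, d) {
    if (!is.finite(d[t])) return(list())
    paths <- list(t)
    for (step in seq_len(d[t])) {
      paths <- do.call(c, lapply(paths, function(p) {
        preds <- which(adj[p[1], ] > 0 & d == d[p[1]] - 1)
        lapply(preds, function(w) c(w, p))
      }))
    }
    paths
  }
  for (s in seq_len(N - 1)) {
    d <- dist_from(s)
    for (t in (s + 1):N) {
      paths <- all_shortest_paths(s, t, d)
      if (!length(paths)) next
      inner <- table(unlist(lapply(paths, function(p) p[-c(1, length(p))])))
      for (v in names(inner)) {
        bt[as.integer(v)] <- bt[as.integer(v)] +
          inner[[v]] / length(paths)
      }
    }
  }
  bt / ((N - 1) * (N - 2) / 2)
}

# --- misc ---------------------------------------------------------------

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

tiny_records <- function() {
  structure(data.frame(
    record_id = c("r1", "r2", "r3"),
    bee_species = c("b1", "b2", "b2"),
    plant_species = c("p1", "p1", "p2"),
    itd_mm = c(2, 3, 3.1),
    fds_mm = c(10, 12, 20),
    interaction_type = "nectar",
    year = 2011L,
    stringsAsFactors = FALSE
  ), class = c("interaction_records", "data.frame"))
}
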