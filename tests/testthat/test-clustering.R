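test_that("trait_dist is the 1-D Euclidean metric", {
  expect_equal(trait_dist(c(1, 4))[1, 2], 3)
  expect_equal(trait_dist(c(2, 2))[1, 2], 0)
  d <- trait_dist(c(1, 2, 5))
  expect_equal(d[1, 3], d[1, 2] + d[2, 3])   # collinearity in 1-D
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("upgma reproduces hand-computed merge orders and heights", {
  t1 <- upgma(c(1.0, 1.1, 5.0))
  expect_equal(t1$height[1], 0.1)
  expect_equal(sort(abs(t1$merge[1, ])), c(1, 2))  # first merge {1.0, 1.1}

  # hand UPGMA on {0,2,10,12}: merges {0,2}, {10,12}, final height
  # mean(|0-10|,|0-12|,|2-10|,|2-12|) = 10
  t2 <- upgma(c(0, 2, 10, 12))
  expect_equal(t2$height, c(2, 2, 10))
})

test_that("upgma equals the brute-force oracle and hclust on random data", {
  withr::with_seed(11, {
    for (n in c(5, 12, 25, 50)) {
      x <- runif(n, 0, 10)
      tree <- upgma(x)
      oracle <- oracle_upgma(x)
      expect_equal(sort(tree$height), sort(oracle$heights),
                   tolerance = 1e-10)
      coph <- as.matrix(stats::cophenetic(tree))
      dimnames(coph) <- NULL
      expect_equal(coph, oracle$cophenetic, tolerance = 1e-10)
      # cross-check against the reference average-linkage implementation
      h <- stats::hclust(stats::dist(x), method = "average")
      expect_equal(tree$height, h$height, tolerance = 1e-10)
    }
  })
})

test_that("upgma is deterministic under ties", {
  x <- c(1, 1, 1, 2, 2, 5)   # heavy ties
  t1 <- upgma(x); t2 <- upgma(x)
  expect_identical(t1$merge, t2$merge)
  expect_identical(t1$height, t2$height)
  # tie-break merges the lowest original indices first
  expect_equal(t1$merge[1, ], c(-1, -2))
})

test_that("cut_clusters covers k extremes, ordering and composition", {
  x <- c(5.0, 1.0, 3.0, 1.1)
  tree <- upgma(x, labels = paste0("i", 1:4))
  all_own <- cut_clusters(tree, 4, x, side = "bee")
  expect_equal(length(unique(all_own$assignment)), 4)
  one <- cut_clusters(tree, 1, x, side = "plant")
  expect_equal(unname(unique(one$assignment)), "F01")
  expect_equal(one$nodes$trait_min, 1.0)
  expect_equal(one$nodes$trait_max, 5.0)

  # node ids ascend with mean trait
  two <- cut_clusters(tree, 2, x, species = c("a", "b", "a", "b"),
                      side = "bee")
  expect_lt(two$nodes$trait_mean[1], two$nodes$trait_mean[2])
  expect_equal(two$nodes$node_id, c("B01", "B02"))
  expect_equal(sum(two$nodes$n), 4)
  expect_error(cut_clusters(tree, 5, x), "k must be")
})

test_that("cuts are contiguous in trait space and hierarchically nested", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      x <- runif(40, 0, 10)
      tree <- upgma(x)
      prev <- NULL
      for (k in c(8, 5, 3, 2)) {
        cl <- cut_clusters(tree, k, x, side = "bee")
        nd <- cl$nodes[order(cl$nodes$trait_mean), ]
        # 1-D contiguity: sorted node ranges must not interleave
        expect_true(all(nd$trait_min[-1] >= nd$trait_max[-k] - 1e-12))
        # refinement: each finer node sits inside exactly one coarser node
        if (!is.null(prev)) {
          tab <- table(prev, cl$assignment)
          expect_true(all(rowSums(tab > 0) == 1))
        }
        prev <- cl$assignment
      }
    }
  })
})

test_that("optimal_k finds clear 1-D blob structure", {
  withr::with_seed(5, {
    blobs <- c(rnorm(12, 0, 0.1), rnorm(12, 5, 0.1), rnorm(12, 10, 0.1))
    res <- optimal_k(blobs)
    expect_equal(res$k_best, 3)
    expect_named(res$votes, c("silhouette", "ch", "db", "dunn", "cindex"))

    two <- c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01))
    expect_equal(optimal_k(two)$k_best, 2)
  })
  expect_error(optimal_k(c(1, 2, 3)), "at least 4")
})
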