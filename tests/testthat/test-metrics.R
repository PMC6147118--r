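test_that("weighted connectance matches hand-derived values", {
  expect_equal(weighted_connectance(matrix(5, 1, 1)), 0.5)
  expect_equal(weighted_connectance(matrix(1, 2, 2)), 0.5)
  expect_equal(weighted_connectance(matrix(c(2, 0, 0, 2), 2)), 0.25)
})

test_that("wnodf matches hand enumeration at the extremes", {
  expect_equal(wnodf(matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3,
                            byrow = TRUE)), 100)
  expect_equal(wnodf(matrix(c(1, 0, 0, 1), 2)), 0)  # equal margins
  expect_error(wnodf(matrix(1:3, 1)), "2x2")
})

test_that("interaction evenness covers uniform, degenerate and hand cases", {
  expect_equal(interaction_evenness(matrix(1, 2, 2)), 1)
  expect_equal(interaction_evenness(matrix(c(4, 0, 0, 0), 2)), 0)
  h <- -(0.5 * log(0.5) + 2 * 0.25 * log(0.25))
  expect_equal(interaction_evenness(matrix(c(2, 1, 1, 0), 2)),
               h / log(4), tolerance = 1e-12)
  # realized-links denominator
  expect_equal(interaction_evenness(matrix(c(2, 1, 1, 0), 2),
                                    "realized_links"),
               h / log(3), tolerance = 1e-12)
})

test_that("h2prime hits its analytic extremes", {
  expect_equal(as.numeric(h2prime(matrix(c(2, 0, 0, 2), 2))), 1)
  # proportional table = outer(margins)/m has H2 = H2max -> 0
  r <- c(6, 2); cc <- c(4, 4)
  prop <- outer(r, cc) / 8
  expect_equal(as.numeric(h2prime(prop)), 0, tolerance = 1e-12)
  deg <- h2prime(matrix(5, 1, 1))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("d_prime is 0 at proportional use and 1 at the feasible extreme", {
  # column 1 proportions equal availability
  m <- matrix(c(6, 3, 2, 1), 2, byrow = TRUE)  # availabilities 9/12, 3/12
  m2 <- matrix(c(3, 6, 1, 2), 2)               # bee1 uses 3:1 = availability
  dp <- d_prime(m2, "bee")
  expect_equal(unname(dp[1]), 0)
  # all visits on the rarest partner, integer-feasible -> d' = 1:
  # plant totals (9, 5); bee 2 places both visits on the rarer plant,
  # which is exactly the dmax allocation
  m3 <- matrix(c(9, 0, 3, 2), 2, byrow = TRUE)
  expect_equal(unname(d_prime(m3, "bee")[2]), 1)
  expect_error(d_prime(matrix(c(1, 0, 0, 0), 2), "bee"), "zero margins")
})

test_that("strength equals hand arithmetic and conserves node counts", {
  expect_equal(unname(node_strength(matrix(c(2, 0, 0, 2), 2), "bee")),
               c(1, 1))
  m <- matrix(c(1, 1, 0, 2), 2, byrow = TRUE)
  expect_equal(unname(node_strength(m, "bee")), c(0.5, 1.5))
  expect_equal(unname(node_strength(m, "plant")), c(1 + 1 / 3, 2 / 3))
  expect_error(node_strength(matrix(c(1, 0, 0, 0), 2), "bee"),
               "zero margins")
})

test_that("dependency conservation holds exactly on random networks", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      m <- random_count_matrix(sample(2:8, 1), sample(2:8, 1))
      expect_equal(sum(node_strength(m, "bee")), nrow(m),
                   tolerance = 1e-12)
      expect_equal(sum(node_strength(m, "plant")), ncol(m),
                   tolerance = 1e-12)
    }
  })
})

test_that("metrics are invariant under joint permutations and scaling", {
  withr::with_seed(55, {
    for (rep in 1:10) {
      m <- random_count_matrix(5, 6)
      pm <- m[sample(5), sample(6)]
      expect_equal(wnodf(pm), wnodf(m), tolerance = 1e-10)
      expect_equal(interaction_evenness(pm), interaction_evenness(m),
                   tolerance = 1e-12)
      expect_equal(as.numeric(h2prime(pm)), as.numeric(h2prime(m)),
                   tolerance = 1e-12)
      expect_equal(weighted_connectance(pm), weighted_connectance(m),
                   tolerance = 1e-12)
      expect_equal(sort(unname(d_prime(pm, "bee"))),
                   sort(unname(d_prime(m, "bee"))), tolerance = 1e-10)
      # scaling all counts by a positive integer
      expect_equal(wnodf(3 * m), wnodf(m), tolerance = 1e-10)
      expect_equal(interaction_evenness(3 * m), interaction_evenness(m),
                   tolerance = 1e-12)
      expect_equal(weighted_connectance(3 * m), weighted_connectance(m),
                   tolerance = 1e-12)
      expect_equal(unname(node_strength(3 * m, "bee")),
                   unname(node_strength(m, "bee")), tolerance = 1e-12)
    }
  })
})

test_that("network_metrics assembles a consistent report", {
  m <- random_count_matrix(4, 5, 60)
  rep <- network_metrics(quant_network(m))
  expect_equal(rep$P, 4); expect_equal(rep$A, 5); expect_equal(rep$m, 60)
  expect_equal(rep$summary["strength_bee", "mean"], 4 / 5,
               tolerance = 1e-12)
  expect_equal(rep$summary["strength_plant", "mean"], 5 / 4,
               tolerance = 1e-12)
})
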