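test_that("build_species_network counts pairs and orders nodes by size", {
  rec <- tiny_records()
  net <- build_species_network(rec)
  # {(p1,b1),(p1,b2),(p2,b2)} -> [[1,1],[0,1]] up to ordering
  expect_equal(sum(net$matrix), 3)
  expect_equal(net$matrix["p1", "b1"], 1)
  expect_equal(net$matrix["p1", "b2"], 1)
  expect_equal(net$matrix["p2", "b2"], 1)
  # bees ordered by ascending mean intertegular distance: b1 (2) < b2 (3.05)
  expect_equal(colnames(net$matrix), c("b1", "b2"))
  # plants by mean display size (no depth column here): p1 (11) < p2 (20)
  expect_equal(rownames(net$matrix), c("p1", "p2"))

  dup <- rec[c(1, 1), ]
  dup$record_id <- c("r1", "r2")
  expect_equal(unname(build_species_network(dup)$matrix), matrix(2, 1, 1))
  expect_error(build_species_network(rec[0, ]), "no interaction")
})

test_that("build_trait_network respects assignments and conserves totals", {
  rec <- tiny_records()
  ptree <- upgma(rec$fds_mm, labels = rec$record_id)
  btree <- upgma(rec$itd_mm, labels = rec$record_id)

  # k = 1 on both sides collapses to a 1x1 matrix [[m]]
  p1 <- cut_clusters(ptree, 1, rec$fds_mm, rec$plant_species, "plant")
  b1 <- cut_clusters(btree, 1, rec$itd_mm, rec$bee_species, "bee")
  expect_equal(unname(build_trait_network(rec, p1, b1)$matrix),
               matrix(3, 1, 1))

  # one node per individual: all cells are ones, m cells nonzero
  pn <- cut_clusters(ptree, 3, rec$fds_mm, rec$plant_species, "plant")
  bn <- cut_clusters(btree, 3, rec$itd_mm, rec$bee_species, "bee")
  net <- build_trait_network(rec, pn, bn)
  expect_true(all(net$matrix %in% c(0, 1)))
  expect_equal(sum(net$matrix), 3)

  # unassigned record errors with its id
  bad <- rec
  bad$record_id[2] <- "missing"
  expect_error(build_trait_network(bad, pn, bn), "missing")
})

test_that("interaction totals are conserved in every mode", {
  withr::with_seed(31, {
    ds <- simulate_community(meadow_preset(n_interactions = 150), seed = 9)
    rec <- predict_functional_traits(ds)
    expect_equal(sum(build_species_network(rec)$matrix), 150)
    pt <- upgma(rec$nhd_mm, labels = rec$record_id)
    bt <- upgma(rec$itd_mm, labels = rec$record_id)
    for (k in c(1, 4, 9)) {
      cp <- cut_clusters(pt, k, rec$nhd_mm, rec$plant_species, "plant")
      cb <- cut_clusters(bt, k, rec$itd_mm, rec$bee_species, "bee")
      expect_equal(sum(build_trait_network(rec, cp, cb)$matrix), 150)
    }
  })
})

test_that("cluster aggregation refines the species matrix when clusters align", {
  # two well-separated species per side: the constrained trait network must
  # equal the species network up to row/column order
  withr::with_seed(13, {
    n <- 60
    rec <- data.frame(
      record_id = sprintf("r%03d", 1:n),
      bee_species = sample(c("small_bee", "big_bee"), n, replace = TRUE),
      plant_species = sample(c("shallow", "deep"), n, replace = TRUE),
      interaction_type = "nectar", year = 2011L,
      stringsAsFactors = FALSE)
    rec$itd_mm <- ifelse(rec$bee_species == "small_bee",
                         rnorm(n, 2, 0.05), rnorm(n, 6, 0.05))
    rec$fds_mm <- ifelse(rec$plant_species == "shallow",
                         rnorm(n, 5, 0.1), rnorm(n, 30, 0.1))
    sp <- build_species_network(rec)
    cp <- cut_clusters(upgma(rec$fds_mm, labels = rec$record_id), 2,
                       rec$fds_mm, rec$plant_species, "plant")
    cb <- cut_clusters(upgma(rec$itd_mm, labels = rec$record_id), 2,
                       rec$itd_mm, rec$bee_species, "bee")
    tr <- build_trait_network(rec, cp, cb)
    expect_equal(unname(tr$matrix), unname(sp$matrix))
    # and each node is pure in species
    expect_true(all(tr$bee_meta$n_species == 1))
  })
})

test_that("quant_network validates its invariants", {
  expect_error(quant_network(matrix(c(1, 0, 0, 0), 2)), "all-zero")
  expect_error(quant_network(matrix(-1, 1, 1)), "finite and >= 0")
  m <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(quant_network(m), "unique")
})
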