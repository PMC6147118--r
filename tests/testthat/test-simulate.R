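test_that("simulate_community is reproducible and shaped by its preset", {
  p <- meadow_preset()
  ds1 <- simulate_community(p, seed = 21)
  ds2 <- simulate_community(p, seed = 21)
  expect_identical(ds1$interactions, ds2$interactions)
  expect_identical(ds1$specimens, ds2$specimens)
  ds3 <- simulate_community(p, seed = 22)
  expect_false(identical(ds1$interactions, ds3$interactions))

  expect_equal(nrow(ds1$interactions), 272L)
  expect_equal(nrow(p$plant), 10L)
  expect_equal(nrow(p$bee), 28L)
  expect_equal(length(ds1$immeasurable), 4L)
  # depths clamped into the preset's 1-10 mm band
  expect_true(all(ds1$interactions$true_nhd_mm >= 1 - 1e-9))
  expect_true(all(ds1$interactions$true_nhd_mm <= 10 + 1e-9))
  # the simulated tables pass community validation
  expect_false(any(validate_community(ds1)$issues$severity == "fatal"))
})

test_that("lambda controls trait matching in the sampled interactions", {
  ds0 <- simulate_community(meadow_preset(lambda = 0), seed = 31)
  r0 <- cor(ds0$interactions$true_proboscis_mm,
            ds0$interactions$true_nhd_mm, method = "spearman")
  expect_lt(abs(r0), 0.2)   # random mixing: no size matching

  ds1 <- simulate_community(meadow_preset(lambda = 1, sigma_match = 0.3),
                            seed = 31)
  r1 <- cor(ds1$interactions$true_proboscis_mm,
            ds1$interactions$true_nhd_mm, method = "spearman")
  expect_gt(r1, 0.5)        # kernel forces matching
})

test_that("trait regressions recover the generating parameters", {
  # refit the bee link on simulated specimen tables across replicates;
  # the average slope error must sit within 3 standard errors
  link <- list(slope = 1.6, intercept = -0.9, noise_sd = 0.6)
  errs <- sapply(1:50, function(s) {
    ds <- simulate_community(meadow_preset(n_interactions = 5), seed = 400 + s)
    bees <- ds$specimens[ds$specimens$side == "bee", ]
    m <- fit_trait_model(bees$predictor_mm, bees$response_mm, "bee")
    se <- summary(lm(response_mm ~ predictor_mm, bees))$coefficients[2, 2]
    c(err = m$slope - link$slope, se = se)
  })
  expect_lt(abs(mean(errs["err", ])), 3 * mean(errs["se", ]) / sqrt(50))
  # and the fits are decent on every replicate
  expect_true(all(abs(errs["err", ]) < 4 * errs["se", ]))
})

test_that("well-separated species are recovered by the constrained cut", {
  withr::with_seed(71, {
    # four bee species with non-overlapping size ranges
    n <- 80
    species <- sample(paste0("sp", 1:4), n, replace = TRUE)
    means <- c(sp1 = 1, sp2 = 4, sp3 = 8, sp4 = 14)
    itd <- rnorm(n, means[species], 0.05)
    cl <- cut_clusters(upgma(itd, labels = as.character(seq_len(n))), 4,
                       itd, species, "bee")
    # perfect agreement: each node holds exactly one species
    tab <- table(cl$assignment, species)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  })
})

test_that("infeasible parameters abort instead of spinning", {
  p <- meadow_preset(lambda = 1, sigma_match = 0.5)
  # pathological bee link: proboscis far outside any nectar depth
  p$bee_link <- list(slope = 1000, intercept = 5000, noise_sd = 0.1)
  expect_error(simulate_community(p, seed = 1), "infeasible")
})

test_that("write_community emits the canonical loader schemas", {
  dir <- tempfile()
  ds <- simulate_community(meadow_preset(n_interactions = 40), seed = 5)
  files <- write_community(ds, dir)
  back <- community_dataset(read_interactions(files["interactions"]),
                            read_specimens(files["specimens"]),
                            immeasurable = readLines(files["immeasurable"]))
  expect_equal(nrow(back$interactions), 40L)
  expect_false(any(validate_community(back)$issues$severity == "fatal"))
  expect_equal(back$interactions$itd_mm, ds$interactions$itd_mm)
})
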