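test_that("fit_trait_model recovers exact and degenerate cases", {
  m <- fit_trait_model(c(1, 2, 3), c(2, 4, 6), "bee")
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)

  expect_warning(mc <- fit_trait_model(c(1, 2, 3), c(1, 1, 1), "plant"),
                 "constant response")
  expect_equal(mc$slope, 0, tolerance = 1e-12)
  expect_equal(mc$r_squared, 0)

  expect_error(fit_trait_model(c(2, 2, 2), c(1, 2, 3), "bee"),
               "degenerate")
  expect_error(fit_trait_model(1, 2, "bee"), "at least 2")
})

test_that("noiseless linear data is recovered to 1e-9 relative tolerance", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      slope <- runif(1, 0.2, 3); intercept <- runif(1, -1, 2)
      x <- runif(20, 1, 8)
      m <- fit_trait_model(x, slope * x + intercept, "bee")
      expect_equal(m$slope, slope, tolerance = 1e-9)
      expect_equal(m$intercept, intercept, tolerance = 1e-9)
    }
  })
})

test_that("predict_nhd applies regressions, the 1 mm floor and the clamp", {
  models <- list(deep = structure(list(side = "plant", species = "deep",
                                       slope = 0.2, intercept = 1,
                                       r_squared = 0.9, n_points = 10),
                                  class = "trait_model"),
                 neg = structure(list(side = "plant", species = "neg",
                                      slope = -1, intercept = 0.5,
                                      r_squared = 0.9, n_points = 10),
                                 class = "trait_model"))
  attr(models, "floors") <- "open"
  rec <- data.frame(record_id = c("a", "b", "c"),
                    plant_species = c("open", "deep", "neg"),
                    fds_mm = c(50, 10, 1))
  expect_warning(out <- predict_nhd(models, rec), "clamped")
  expect_identical(out$nhd_mm, c(1.0, 3.0, 0.1))
  expect_identical(out$nhd_source, c("floor", "regression", "regression"))

  # floor species always get exactly 1.0 regardless of display size
  rec2 <- data.frame(record_id = "z", plant_species = "open", fds_mm = 999)
  expect_identical(predict_nhd(models, rec2)$nhd_mm, 1.0)

  rec3 <- data.frame(record_id = "q", plant_species = "unknown", fds_mm = 5)
  expect_error(predict_nhd(models, rec3), "unknown")
})

test_that("predict_proboscis is linear, clamped and monotone", {
  m <- structure(list(side = "bee", species = "pooled", slope = 1.5,
                      intercept = -0.5, r_squared = 0.8, n_points = 30),
                 class = "trait_model")
  expect_equal(predict_proboscis(m, 2), 2.5)
  expect_warning(v <- predict_proboscis(m, 0.1), "clamped")
  expect_equal(v, 0.1)
  grid <- seq(1, 6, by = 0.5)
  expect_true(all(diff(predict_proboscis(m, grid)) > 0))
})

test_that("refit on noisy synthetic data stays within 3 SE of truth", {
  withr::with_seed(7, {
    itd <- runif(50, 1, 6)
    pl <- 1.4 * itd + 0.1 + rnorm(50, 0, 0.05)
    m <- fit_trait_model(itd, pl, "bee")
    se_slope <- summary(lm(pl ~ itd))$coefficients["itd", "Std. Error"]
    expect_lt(abs(m$slope - 1.4), 3 * se_slope)
    grid <- seq(1.5, 5.5, by = 1)
    pred <- predict_proboscis(m, grid)
    expect_true(all(abs(pred - (1.4 * grid + 0.1)) < 0.1))
  })
})

test_that("summarize_fits computes mean and SD of R-squared", {
  mk <- function(r2) structure(list(r_squared = r2), class = "trait_model")
  s <- summarize_fits(list(mk(0.4), mk(0.6)))
  expect_equal(s$mean_r2, 0.5)
  expect_equal(s$sd_r2, sd(c(0.4, 0.6)), tolerance = 1e-12)
  s1 <- summarize_fits(list(mk(0.9)))
  expect_equal(s1$mean_r2, 0.9)
  expect_equal(s1$sd_r2, 0)
  expect_false(s1$sd_defined)
  expect_error(summarize_fits(list()), "no models")
})
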