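#' Simulation parameters for a synthetic bee-flower community
#'
#' Describes a community at the individual level: per-species trait
#' distributions, the linear trait links used for imputation, the
#' size-matching interaction kernel, and sampling effort.  Interactions
#' are sampled with probability proportional to
#' `(1 - lambda) + lambda * exp(-(PL - NHD)^2 / (2 * sigma_match^2))`,
#' so `lambda = 0` is random mixing and `lambda = 1` pure size matching.
#'
#' @param plant data.frame with one row per plant species: `species`,
#'   `fds_mean`, `fds_sd` (floral display size, mm), `nhd_slope`,
#'   `nhd_intercept`, `nhd_noise_sd` (the within-species depth-on-display
#'   regression), `abundance` (relative visit rate), `floor` (logical:
#'   open flower, nectar holder depth fixed at 1 mm).
#' @param bee data.frame with one row per bee species: `species`,
#'   `itd_mean`, `itd_sd` (intertegular distance, mm), `abundance`.
#' @param bee_link list `slope`, `intercept`, `noise_sd`: proboscis length
#'   as a linear function of intertegular distance (mm per mm), shared by
#'   all species.
#' @param sigma_match kernel width (mm): how far a proboscis may miss the
#'   nectar holder depth before the visit probability decays.
#' @param lambda matching strength in `[0, 1]`.
#' @param n_interactions number of interaction records to emit.
#' @param n_bee_specimens,n_plant_specimens specimens measured per species
#'   for the calibration table.
#' @param nhd_range optional `c(lo, hi)`: clamp simulated depths into this
#'   range (mm).
#' @param seed default seed used by [simulate_community()].
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(plant, bee,
                       bee_link = list(slope = 1.6, intercept = -0.9,
                                       noise_sd = 0.6),
                       sigma_match = 0.5, lambda = 1,
                       n_interactions = 272,
                       n_bee_specimens = 5, n_plant_specimens = 15,
                       nhd_range = NULL, seed = 1) {
  stopifnot(is.data.frame(plant), is.data.frame(bee),
            lambda >= 0, lambda <= 1, n_interactions >= 1,
            sigma_match > 0,
            all(plant$fds_sd >= 0), all(bee$itd_sd >= 0),
            all(plant$abundance > 0), all(bee$abundance > 0))
  structure(list(plant = plant, bee = bee, bee_link = bee_link,
                 sigma_match = sigma_match, lambda = lambda,
                 n_interactions = n_interactions,
                 n_bee_specimens = n_bee_specimens,
                 n_plant_specimens = n_plant_specimens,
                 nhd_range = nhd_range, seed = seed),
            class = "sim_params")
}

#' Default parameters emulating a small temperate meadow community
#'
#' Ten plant species (four of them open flowers with the 1 mm depth
#' floor, the rest spanning mean nectar holder depths of 2-10 mm) and 28
#' bee species with mean intertegular distances spread over 1.4-6.4 mm;
#' 272 interaction records; geometric rank-abundance on both sides
#' (ratios 0.8 and 0.85) so a few species dominate, as in real transect
#' data; full size matching (`lambda = 1`) with a 0.5 mm kernel;
#' simulated depths clamped into 1-10 mm.
#'
#' @param ... overrides forwarded to [sim_params()] (e.g. `lambda = 0`,
#'   `seed`).
#' @return a `sim_params` object.
#' @export
meadow_preset <- function(...) {
  n_p <- 10; n_b <- 28
  # fixed permutations decouple abundance rank from size rank
  perm_p <- c(3L, 7L, 1L, 9L, 5L, 2L, 8L, 4L, 10L, 6L)
  perm_b <- c(15L, 3L, 22L, 9L, 27L, 6L, 18L, 1L, 12L, 24L, 8L, 20L, 4L,
              16L, 28L, 11L, 2L, 25L, 14L, 7L, 19L, 26L, 10L, 23L, 5L,
              17L, 13L, 21L)
  fds_mean <- c(25, 35, 15, 45, seq(8, 50, length.out = 6))
  fds_sd <- 0.18 * fds_mean
  nhd_target <- c(rep(1, 4), seq(2, 10, length.out = 6))
  slope <- c(rep(0, 4), rep(0.18, 6))
  noise <- slope * fds_sd                 # within-species R2 about 0.5
  plant <- data.frame(
    species = sprintf("plant_%02d", seq_len(n_p)),
    fds_mean = fds_mean, fds_sd = fds_sd,
    nhd_slope = slope,
    nhd_intercept = nhd_target - slope * fds_mean,
    nhd_noise_sd = noise,
    abundance = (0.8^(seq_len(n_p) - 1))[perm_p],
    floor = c(rep(TRUE, 4), rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )
  itd_mean <- seq(1.4, 6.4, length.out = n_b)
  bee <- data.frame(
    species = sprintf("bee_%02d", seq_len(n_b)),
    itd_mean = itd_mean, itd_sd = 0.07 * itd_mean,
    abundance = (0.85^(seq_len(n_b) - 1))[perm_b],
    stringsAsFactors = FALSE
  )
  sim_params(plant = plant, bee = bee, nhd_range = c(1, 10), ...)
}

# truncated-normal draws (resampling below `lower`)
rnorm_trunc <- function(n, mean, sd, lower = 0.1) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lower)
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- lower; break }
  }
  x
}

#' Simulate an individual-level bee-flower community
#'
#' Draws individual bees (species by relative abundance, intertegular
#' distance from a truncated normal, proboscis length from the shared
#' linear link plus noise) and individual flowers (floral display size,
#' nectar holder depth from the per-species link, or exactly 1 mm for
#' floor species), then accepts candidate bee-flower pairs with the
#' size-matching kernel until `n_interactions` records are collected.
#' Each accepted record is a fresh individual on both sides.  Also emits
#' the specimen calibration tables.  Fully reproducible given the seed.
#'
#' @param params a [sim_params()] object, e.g. from [meadow_preset()].
#' @param seed integer; defaults to `params$seed`.  The caller's RNG
#'   state is preserved.
#' @return a [community_dataset()].
#' @export
simulate_community <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    pl <- params$plant; be <- params$bee; link <- params$bee_link

    specimens <- rbind(
      do.call(rbind, lapply(seq_len(nrow(be)), function(i) {
        itd <- rnorm_trunc(params$n_bee_specimens, be$itd_mean[i],
                           be$itd_sd[i])
        plen <- pmax(0.1, link$slope * itd + link$intercept +
                       stats::rnorm(length(itd), 0, link$noise_sd))
        data.frame(side = "bee", species = be$species[i],
                   predictor_mm = itd, response_mm = plen,
                   stringsAsFactors = FALSE)
      })),
      do.call(rbind, lapply(which(!pl$floor), function(i) {
        fds <- rnorm_trunc(params$n_plant_specimens, pl$fds_mean[i],
                           pl$fds_sd[i], lower = 1)
        nhd <- pmax(0.1, pl$nhd_slope[i] * fds + pl$nhd_intercept[i] +
                      stats::rnorm(length(fds), 0, pl$nhd_noise_sd[i]))
        data.frame(side = "plant", species = pl$species[i],
                   predictor_mm = fds, response_mm = nhd,
                   stringsAsFactors = FALSE)
      }))
    )
    class(specimens) <- c("specimen_measurements", "data.frame")

    n <- params$n_interactions
    acc <- vector("list", 0)
    got <- 0L
    tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 200L) stop("infeasible simulation parameters: ",
                             "acceptance probability is (close to) zero")
      batch <- max(4L * (n - got), 100L)
      bi <- sample.int(nrow(be), batch, replace = TRUE, prob = be$abundance)
      pi <- sample.int(nrow(pl), batch, replace = TRUE, prob = pl$abundance)
      itd <- rnorm_trunc(batch, be$itd_mean[bi], be$itd_sd[bi])
      plen <- pmax(0.1, link$slope * itd + link$intercept +
                     stats::rnorm(batch, 0, link$noise_sd))
      fds <- rnorm_trunc(batch, pl$fds_mean[pi], pl$fds_sd[pi], lower = 1)
      nhd <- ifelse(pl$floor[pi], 1.0,
                    pmax(0.1, pl$nhd_slope[pi] * fds + pl$nhd_intercept[pi] +
                           stats::rnorm(batch, 0, pl$nhd_noise_sd[pi])))
      if (!is.null(params$nhd_range)) {
        nhd <- ifelse(pl$floor[pi], 1.0,
                      pmin(params$nhd_range[2],
                           pmax(params$nhd_range[1], nhd)))
      }
      p_acc <- (1 - params$lambda) +
        params$lambda * exp(-(plen - nhd)^2 / (2 * params$sigma_match^2))
      ok <- which(stats::runif(batch) < p_acc)
      if (length(ok)) {
        take <- ok[seq_len(min(length(ok), n - got))]
        acc[[length(acc) + 1L]] <- data.frame(
          bee_species = be$species[bi[take]],
          plant_species = pl$species[pi[take]],
          itd_mm = itd[take], fds_mm = fds[take],
          true_proboscis_mm = plen[take], true_nhd_mm = nhd[take],
          stringsAsFactors = FALSE)
        got <- got + length(take)
      }
    }
    rec <- do.call(rbind, acc)
    rec$record_id <- sprintf("r%05d", seq_len(n))
    rec$interaction_type <- sample(
      c("nectar", "pollen", "nectar_and_pollen", "robbing"), n,
      replace = TRUE, prob = c(0.55, 0.25, 0.18, 0.02))
    rec$year <- sample(c(2011L, 2012L), n, replace = TRUE)
    rec <- rec[, c("record_id", "bee_species", "plant_species", "itd_mm",
                   "fds_mm", "interaction_type", "year",
                   "true_proboscis_mm", "true_nhd_mm")]
    class(rec) <- c("interaction_records", "data.frame")
    attr(rec, "issues") <- new_issues()
    community_dataset(rec, specimens,
                      immeasurable = pl$species[pl$floor])
  })
}

#' Write a simulated community to the canonical CSV schemas
#'
#' @param ds a [community_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_community <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ip <- file.path(dir, "interactions.csv")
  sp <- file.path(dir, "specimens.csv")
  fp <- file.path(dir, "immeasurable.txt")
  cols <- c("record_id", "bee_species", "plant_species", "itd_mm",
            "fds_mm", "interaction_type", "year")
  utils::write.csv(as.data.frame(ds$interactions)[, cols], ip,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ds$specimens), sp, row.names = FALSE)
  writeLines(ds$immeasurable, fp)
  invisible(c(interactions = ip, specimens = sp, immeasurable = fp))
}
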