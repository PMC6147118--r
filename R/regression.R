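#' Fit a linear trait-imputation model
#'
#' Ordinary least squares of a response size trait on a predictor size
#' trait, both in millimetres: proboscis length on intertegular distance
#' for bees, nectar holder depth on floral display size for plants.
#' R-squared is the plain (unadjusted) coefficient of determination
#' `1 - SS_res/SS_tot`; a constant response gives `r_squared = 0` with a
#' warning, a constant predictor is a degenerate regression and errors.
#'
#' @param predictor_mm,response_mm numeric vectors of equal length >= 2.
#' @param side `"bee"` or `"plant"`.
#' @param species taxon label, or `"pooled"`.
#' @return a list of class `trait_model`: `side`, `species`, `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_trait_model <- function(predictor_mm, response_mm,
                            side = c("bee", "plant"), species = "pooled") {
  side <- match.arg(side)
  x <- as.numeric(predictor_mm); y <- as.numeric(response_mm)
  if (length(x) != length(y)) stop("predictor and response lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::var(x) == 0) stop("degenerate regression: constant predictor")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: r_squared set to 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  structure(list(side = side, species = species, slope = slope,
                 intercept = intercept, r_squared = r2,
                 n_points = length(x)),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("trait model [%s/%s]: response = %.4f * predictor + %.4f  (R2 = %.3f, n = %d)\n",
              x$side, x$species, x$slope, x$intercept, x$r_squared,
              x$n_points))
  invisible(x)
}

#' Fit all trait models for a community
#'
#' Fits one pooled bee regression (proboscis length ~ intertegular
#' distance across all bee specimens) and one plant regression per
#' measurable species (nectar holder depth ~ floral display size).
#' Species listed as immeasurable get the 1 mm depth floor instead of a
#' model.
#'
#' @param ds a [community_dataset()].
#' @param per_species_bee fit one bee model per species instead of the
#'   pooled default (requires >= 2 specimens per species).
#' @return list of class `trait_models`: `bee` (a `trait_model`, or a named
#'   list when `per_species_bee`), `plant` (named list of `trait_model`),
#'   `floors` (character vector of floor species).
#' @export
fit_trait_models <- function(ds, per_species_bee = FALSE) {
  stopifnot(inherits(ds, "community_dataset"))
  sp <- ds$specimens
  bees <- sp[sp$side == "bee", ]
  plants <- sp[sp$side == "plant", ]
  if (per_species_bee) {
    bee <- lapply(split(bees, bees$species), function(d) {
      fit_trait_model(d$predictor_mm, d$response_mm, "bee", d$species[1])
    })
  } else {
    bee <- fit_trait_model(bees$predictor_mm, bees$response_mm, "bee")
  }
  plant <- lapply(split(plants, plants$species), function(d) {
    fit_trait_model(d$predictor_mm, d$response_mm, "plant", d$species[1])
  })
  structure(list(bee = bee, plant = plant, floors = ds$immeasurable),
            class = "trait_models")
}

# smallest admissible predicted size: keeps downstream 1-D distances
# meaningful when a regression extrapolates below zero
.TRAIT_FLOOR_MM <- 0.1

#' Predict nectar holder depth for interaction records
#'
#' Floor species (open flowers) receive exactly 1.0 mm; all other species
#' use their fitted per-species regression on the record's floral display
#' size.  Predictions below 0.1 mm are clamped with a warning.
#'
#' @param models a `trait_models` object (or a named list of plant
#'   `trait_model`s plus a `floors` character vector).
#' @param records an `interaction_records` data.frame.
#' @return data.frame `record_id`, `nhd_mm`, `nhd_source`
#'   (`"regression"` or `"floor"`).
#' @export
predict_nhd <- function(models, records) {
  plant_models <- if (inherits(models, "trait_models")) models$plant else models
  floors <- if (inherits(models, "trait_models")) models$floors else
    attr(models, "floors") %||% character()
  n <- nrow(records)
  nhd <- numeric(n); src <- character(n)
  clamped <- 0L
  for (i in seq_len(n)) {
    s <- records$plant_species[i]
    if (s %in% floors) {
      nhd[i] <- 1.0; src[i] <- "floor"
    } else if (!is.null(plant_models[[s]])) {
      m <- plant_models[[s]]
      v <- m$slope * records$fds_mm[i] + m$intercept
      if (v < .TRAIT_FLOOR_MM) { v <- .TRAIT_FLOOR_MM; clamped <- clamped + 1L }
      nhd[i] <- v; src[i] <- "regression"
    } else {
      stop("plant species '", s, "' has neither a depth model nor a floor flag")
    }
  }
  if (clamped > 0) {
    warning(clamped, " depth prediction(s) clamped at ",
            .TRAIT_FLOOR_MM, " mm")
  }
  data.frame(record_id = records$record_id, nhd_mm = nhd, nhd_source = src,
             stringsAsFactors = FALSE)
}

#' Predict proboscis length from intertegular distance
#'
#' @param model the pooled bee `trait_model`.
#' @param itd_mm numeric vector of intertegular distances (mm).
#' @return numeric vector of predicted proboscis lengths (mm), clamped
#'   below at 0.1 mm with a warning.
#' @export
predict_proboscis <- function(model, itd_mm) {
  stopifnot(inherits(model, "trait_model"))
  v <- model$slope * as.numeric(itd_mm) + model$intercept
  low <- v < .TRAIT_FLOOR_MM
  if (any(low)) {
    warning(sum(low), " proboscis prediction(s) clamped at ",
            .TRAIT_FLOOR_MM, " mm")
    v[low] <- .TRAIT_FLOOR_MM
  }
  v
}

#' Attach predicted functional size traits to interaction records
#'
#' Adds `nhd_mm`/`nhd_source` (predicted nectar holder depth of the visited
#' flower) and `proboscis_mm` (predicted proboscis length of the bee) to
#' every record.  The clustering stage uses `nhd_mm` (plants) and `itd_mm`
#' (bees) as the functional size traits.
#'
#' @param ds a [community_dataset()].
#' @param models the result of [fit_trait_models()]; fitted from `ds` when
#'   `NULL`.
#' @return the interaction data.frame with prediction columns appended.
#' @export
predict_functional_traits <- function(ds, models = NULL) {
  if (is.null(models)) models <- fit_trait_models(ds)
  rec <- ds$interactions
  nhd <- predict_nhd(models, rec)
  rec$nhd_mm <- nhd$nhd_mm
  rec$nhd_source <- nhd$nhd_source
  bee_model <- if (inherits(models$bee, "trait_model")) models$bee else NULL
  if (is.null(bee_model)) {
    rec$proboscis_mm <- vapply(seq_len(nrow(rec)), function(i) {
      m <- models$bee[[rec$bee_species[i]]]
      if (is.null(m)) stop("no bee model for species '", rec$bee_species[i], "'")
      predict_proboscis(m, rec$itd_mm[i])
    }, numeric(1))
  } else {
    rec$proboscis_mm <- predict_proboscis(bee_model, rec$itd_mm)
  }
  rec
}

#' Summarize R-squared over a set of trait models
#'
#' @param models list of `trait_model`s (e.g. the per-species plant models).
#' @return list `mean_r2`, `sd_r2`, `n_models`, `sd_defined` (`FALSE` when
#'   a single model makes the sample SD undefined; `sd_r2` is then 0).
#' @export
summarize_fits <- function(models) {
  if (inherits(models, "trait_model")) models <- list(models)
  if (length(models) == 0) stop("no models to summarize")
  r2 <- vapply(models, function(m) m$r_squared, numeric(1))
  sd_def <- length(r2) > 1
  list(mean_r2 = mean(r2), sd_r2 = if (sd_def) stats::sd(r2) else 0,
       n_models = length(r2), sd_defined = sd_def)
}

#' Export fitted trait models as JSON
#'
#' @param models a `trait_models` object or list of `trait_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_models <- function(models, path) {
  flatten <- function(m) m[c("side", "species", "slope", "intercept",
                             "r_squared", "n_points")]
  if (inherits(models, "trait_models")) {
    bee <- if (inherits(models$bee, "trait_model")) list(flatten(models$bee))
           else lapply(models$bee, flatten)
    obj <- list(bee = bee, plant = lapply(unname(models$plant), flatten),
                floors = models$floors)
  } else {
    obj <- lapply(unname(models), flatten)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
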