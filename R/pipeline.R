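#' Pipeline configuration
#'
#' Collects every tunable of the full comparison in one object.  Input is
#' either a pair of CSV paths (plus the immeasurable-species list) or a
#' [sim_params()] preset; every stochastic stage derives its seed from
#' `seed`.
#'
#' @param interactions,specimens CSV paths (see [read_interactions()],
#'   [read_specimens()]), or `NULL` when simulating.
#' @param immeasurable character vector of floor plant species (ignored
#'   when simulating; the preset carries its own).
#' @param sim a `sim_params` object, or `NULL` when reading files.
#' @param seed master seed.
#' @param null_n Patefield ensemble size for the Cq/IE/H2' z-tests
#'   (0 disables null testing).
#' @param nestedness list `enabled`, `start`, `max_n`, `tol` for the
#'   adaptive WNODF nulls (see [nestedness_significance()]).
#' @param k_range candidate k values for the unconstrained cut.
#' @param ie_denominator passed to [interaction_evenness()].
#' @param drop_robbing drop nectar-robbing records.
#' @param column_map passed to the readers.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(interactions = NULL, specimens = NULL,
                            immeasurable = character(), sim = NULL,
                            seed = 1, null_n = 1000,
                            nestedness = list(enabled = TRUE, start = 500,
                                              max_n = 10000, tol = 0.005),
                            k_range = NULL,
                            ie_denominator = "all_cells",
                            drop_robbing = FALSE, column_map = NULL) {
  if (is.null(sim) && (is.null(interactions) || is.null(specimens))) {
    stop("provide either input file paths or a sim_params object")
  }
  structure(list(interactions = interactions, specimens = specimens,
                 immeasurable = immeasurable, sim = sim, seed = seed,
                 null_n = null_n, nestedness = nestedness,
                 k_range = k_range, ie_denominator = ie_denominator,
                 drop_robbing = drop_robbing, column_map = column_map),
            class = "pipeline_config")
}

#' Run the full species-versus-trait network comparison
#'
#' Executes every stage in order: load or simulate the community, validate
#' it, fit the trait regressions, predict functional size for every
#' record, cluster each side (constrained to the observed species counts,
#' and unconstrained at the validity-index optimum), build the three
#' quantitative networks (species-based, constrained trait-based,
#' unconstrained trait-based), compute metrics, run the Patefield z-tests
#' for Cq/IE/H2' and the adaptive CRT/CCT/RCTA nulls for WNODF, and
#' compute centrality.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `comparison_report` with elements `validation`,
#'   `models`, `records`, `clusters`, `networks`, `metrics`, `nulls`,
#'   `centrality`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ds <- stage("load", {
    if (!is.null(config$sim)) {
      simulate_community(config$sim, seed = config$seed)
    } else {
      community_dataset(
        read_interactions(config$interactions, config$column_map,
                          drop_robbing = config$drop_robbing),
        read_specimens(config$specimens, config$column_map),
        immeasurable = config$immeasurable)
    }
  })
  val <- stage("validate", {
    v <- validate_community(ds)
    if (any(v$issues$severity == "fatal")) {
      stop(paste(v$issues$message[v$issues$severity == "fatal"],
                 collapse = "; "))
    }
    v
  })
  models <- stage("fit-traits", fit_trait_models(ds))
  rec <- stage("predict", predict_functional_traits(ds, models))

  clusters <- stage("cluster", {
    n_plant <- length(unique(rec$plant_species))
    n_bee <- length(unique(rec$bee_species))
    ptree <- upgma(rec$nhd_mm, labels = rec$record_id)
    btree <- upgma(rec$itd_mm, labels = rec$record_id)
    kp <- optimal_k(rec$nhd_mm, config$k_range)
    kb <- optimal_k(rec$itd_mm, config$k_range)
    list(
      constrained = list(
        plant = cut_clusters(ptree, n_plant, rec$nhd_mm,
                             rec$plant_species, "plant"),
        bee = cut_clusters(btree, n_bee, rec$itd_mm,
                           rec$bee_species, "bee")),
      unconstrained = list(
        plant = cut_clusters(ptree, kp$k_best, rec$nhd_mm,
                             rec$plant_species, "plant"),
        bee = cut_clusters(btree, kb$k_best, rec$itd_mm,
                           rec$bee_species, "bee")),
      optimal_k = list(plant = kp, bee = kb))
  })

  networks <- stage("build", list(
    species = build_species_network(rec),
    constrained = build_trait_network(rec, clusters$constrained$plant,
                                      clusters$constrained$bee),
    unconstrained = build_trait_network(rec, clusters$unconstrained$plant,
                                        clusters$unconstrained$bee)))

  metrics <- stage("metrics", lapply(networks, network_metrics,
                                     ie_denominator = config$ie_denominator))

  nulls <- stage("nulls", {
    if (config$null_n > 0) {
      lapply(seq_along(networks), function(i) {
        net <- networks[[i]]
        mseed <- (config$seed + 100 * i) %% .Machine$integer.max
        zt <- function(fn, obs, off) {
          zscore_test(obs, null_distribution(net, fn, "r2dtable",
                                             n = config$null_n,
                                             seed = mseed + off))
        }
        res <- list(
          Cq = zt(weighted_connectance, metrics[[i]]$Cq, 1),
          IE = zt(function(m) interaction_evenness(m, config$ie_denominator),
                  metrics[[i]]$IE, 2),
          H2prime = zt(function(m) as.numeric(h2prime(m)),
                       metrics[[i]]$H2prime, 3))
        if (isTRUE(config$nestedness$enabled) &&
            nrow(as_qmatrix(net)) >= 2 && ncol(as_qmatrix(net)) >= 2) {
          res$WNODF <- nestedness_significance(
            net, start = config$nestedness$start,
            max_n = config$nestedness$max_n, tol = config$nestedness$tol,
            seed = mseed + 10)
        }
        res
      }) |> stats::setNames(names(networks))
    } else NULL
  })

  centrality <- stage("centrality", lapply(networks, node_centrality))

  structure(list(validation = val, models = models, records = rec,
                 clusters = clusters, networks = networks,
                 metrics = metrics, nulls = nulls,
                 centrality = centrality, seed = config$seed),
            class = "comparison_report")
}

#' Side-by-side comparison table for a pipeline report
#'
#' One row per network parameter (P, A, Cq, IE, H2', WNODF and the
#' mean +/- SD of the node-level d' and strength per side), one column per
#' network mode, plus the change from the species-based to the constrained
#' trait-based network.
#'
#' @param report a `comparison_report` from [run_pipeline()].
#' @param digits rounding for display columns.
#' @return a data.frame.
#' @export
compare_networks <- function(report, digits = 3) {
  stopifnot(inherits(report, "comparison_report"))
  modes <- names(report$metrics)
  row_of <- function(f) vapply(report$metrics, f, numeric(1))
  tab <- rbind(
    P = row_of(function(m) m$P),
    A = row_of(function(m) m$A),
    Cq = row_of(function(m) m$Cq),
    IE = row_of(function(m) m$IE),
    H2prime = row_of(function(m) m$H2prime),
    WNODF = row_of(function(m) m$WNODF),
    d_prime_bee_mean = row_of(function(m) m$summary["d_prime_bee", "mean"]),
    d_prime_bee_sd = row_of(function(m) m$summary["d_prime_bee", "sd"]),
    d_prime_plant_mean = row_of(function(m) m$summary["d_prime_plant", "mean"]),
    d_prime_plant_sd = row_of(function(m) m$summary["d_prime_plant", "sd"]),
    strength_bee_mean = row_of(function(m) m$summary["strength_bee", "mean"]),
    strength_bee_sd = row_of(function(m) m$summary["strength_bee", "sd"]),
    strength_plant_mean = row_of(function(m) m$summary["strength_plant", "mean"]),
    strength_plant_sd = row_of(function(m) m$summary["strength_plant", "sd"])
  )
  out <- as.data.frame(round(tab, digits))
  names(out) <- modes
  if (all(c("species", "constrained") %in% modes)) {
    out$delta_constrained <- round(out$constrained - out$species, digits)
  }
  out <- cbind(parameter = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("species vs trait-based network comparison (seed", x$seed, ")\n\n")
  print(compare_networks(x), row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  sig <- function(s) if (is.null(s)) NULL else
    lapply(s, function(v) {
      if (inherits(v, "significance_test")) {
        v[c("observed", "null_mean", "null_sd", "n", "z", "z_reversed",
            "p_two_sided")]
      } else {
        lapply(v, function(w) w[c("observed", "null_mean", "null_sd", "n",
                                  "z", "z_reversed", "p_two_sided",
                                  "n_final", "model")])
      }
    })
  obj <- list(
    seed = report$seed,
    validation = report$validation[c("n_records", "n_bee_species",
                                     "n_plant_species")],
    comparison = compare_networks(report, digits = 6),
    nulls = if (!is.null(report$nulls)) lapply(report$nulls, sig),
    centrality = lapply(report$centrality, as.data.frame)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
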