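#' Read an interaction-record table
#'
#' Loads a CSV with one row per observed individual bee-flower interaction.
#' Expected columns (renameable through `column_map`):
#' `record_id, bee_species, plant_species, itd_mm, fds_mm,
#' interaction_type, year`.  `itd_mm` is the bee's intertegular distance and
#' `fds_mm` the maximum floral display size of the visited flower, both in
#' millimetres.
#'
#' The loader is total: every input row either becomes a record or is
#' rejected with an enumerated issue; the two counts always reconcile with
#' the row count of the file.  Unknown `interaction_type` values are kept
#' verbatim and flagged with a warning-level issue.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping the canonical
#'   column names to the names actually used in the file, e.g.
#'   `c(itd_mm = "thorax_width")`.
#' @param drop_robbing if `TRUE`, records with `interaction_type ==
#'   "robbing"` are dropped (with an info issue); they are retained by
#'   default.
#' @return a `data.frame` of class `interaction_records` with attribute
#'   `issues` (a data.frame of `severity`, `message`).
#' @export
read_interactions <- function(path, column_map = NULL, drop_robbing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  req <- c("record_id", "bee_species", "plant_species", "itd_mm", "fds_mm",
           "interaction_type", "year")
  raw <- remap_columns(raw, req, column_map)
  issues <- new_issues()

  n <- nrow(raw)
  keep <- rep(TRUE, n)
  itd <- suppressWarnings(as.numeric(raw$itd_mm))
  fds <- suppressWarnings(as.numeric(raw$fds_mm))
  yr  <- suppressWarnings(as.integer(raw$year))
  for (i in seq_len(n)) {
    bad <- character()
    if (is.na(itd[i]) || itd[i] <= 0) bad <- c(bad, "itd_mm")
    if (is.na(fds[i]) || fds[i] <= 0) bad <- c(bad, "fds_mm")
    if (!nzchar(raw$record_id[i]))    bad <- c(bad, "record_id")
    if (length(bad)) {
      keep[i] <- FALSE
      issues <- add_issue(issues, "reject",
        sprintf("row %d rejected: invalid %s", i, paste(bad, collapse = ", ")))
    }
  }
  dup <- duplicated(raw$record_id) & keep
  if (any(dup)) {
    keep[dup] <- FALSE
    issues <- add_issue(issues, "reject",
      sprintf("row %d rejected: duplicate record_id '%s'",
              which(dup), raw$record_id[dup]))
  }

  known <- c("nectar", "pollen", "nectar_and_pollen", "robbing")
  unk <- setdiff(unique(raw$interaction_type[keep]), known)
  for (u in unk) {
    issues <- add_issue(issues, "warning",
      sprintf("unknown interaction_type '%s' kept verbatim", u))
  }
  if (drop_robbing) {
    rb <- keep & raw$interaction_type == "robbing"
    if (any(rb)) {
      keep[rb] <- FALSE
      issues <- add_issue(issues, "info",
                          sprintf("%d robbing record(s) dropped", sum(rb)))
    }
  }

  rec <- data.frame(
    record_id = raw$record_id[keep],
    bee_species = raw$bee_species[keep],
    plant_species = raw$plant_species[keep],
    itd_mm = itd[keep],
    fds_mm = fds[keep],
    interaction_type = raw$interaction_type[keep],
    year = yr[keep],
    stringsAsFactors = FALSE
  )
  class(rec) <- c("interaction_records", "data.frame")
  attr(rec, "issues") <- issues
  rec
}

#' Read a specimen-trait table
#'
#' Loads the regression-calibration table: one row per measured specimen,
#' with columns `side` (`"bee"` or `"plant"`), `species`, `predictor_mm`
#' (intertegular distance for bees, floral display size for plants) and
#' `response_mm` (proboscis length for bees, nectar holder depth for
#' plants).
#'
#' @inheritParams read_interactions
#' @return a `data.frame` of class `specimen_measurements` with attribute
#'   `issues`.
#' @export
read_specimens <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  req <- c("side", "species", "predictor_mm", "response_mm")
  raw <- remap_columns(raw, req, column_map)
  issues <- new_issues()
  pred <- suppressWarnings(as.numeric(raw$predictor_mm))
  resp <- suppressWarnings(as.numeric(raw$response_mm))
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!raw$side[i] %in% c("bee", "plant")) {
      keep[i] <- FALSE
      issues <- add_issue(issues, "reject",
        sprintf("row %d rejected: side must be 'bee' or 'plant'", i))
    } else if (is.na(pred[i]) || pred[i] <= 0 ||
               is.na(resp[i]) || resp[i] <= 0) {
      keep[i] <- FALSE
      issues <- add_issue(issues, "reject",
        sprintf("row %d rejected: non-positive or non-numeric measurement", i))
    }
  }
  sp <- data.frame(side = raw$side[keep], species = raw$species[keep],
                   predictor_mm = pred[keep], response_mm = resp[keep],
                   stringsAsFactors = FALSE)
  class(sp) <- c("specimen_measurements", "data.frame")
  attr(sp, "issues") <- issues
  sp
}

#' Bundle interactions, specimens and the immeasurable-species set
#'
#' @param interactions an `interaction_records` data.frame.
#' @param specimens a `specimen_measurements` data.frame.
#' @param immeasurable character vector of plant species whose nectar
#'   holder depth is effectively too short to measure; they receive a fixed
#'   1 mm depth instead of a regression.
#' @return a list of class `community_dataset`.
#' @export
community_dataset <- function(interactions, specimens,
                              immeasurable = character()) {
  structure(list(interactions = interactions, specimens = specimens,
                 immeasurable = unique(as.character(immeasurable))),
            class = "community_dataset")
}

#' Validate a community dataset
#'
#' Checks the structural invariants the downstream stages rely on: every
#' plant species in the interaction table either is flagged immeasurable
#' (1 mm floor) or has at least two plant specimens for its depth
#' regression, and the bee side has at least two specimens overall for the
#' pooled proboscis regression.
#'
#' @param ds a [community_dataset()].
#' @return a list of class `validation_report` with counts and an `issues`
#'   data.frame (`severity` in `fatal`/`warning`/`info`).
#' @export
validate_community <- function(ds) {
  stopifnot(inherits(ds, "community_dataset"))
  ints <- ds$interactions
  issues <- new_issues()
  for (src in list(ints, ds$specimens)) {
    ii <- attr(src, "issues")
    if (!is.null(ii) && nrow(ii)) issues <- rbind(issues, ii)
  }
  n_records <- nrow(ints)
  if (n_records == 0L) {
    issues <- add_issue(issues, "fatal", "no interaction records")
  }
  plant_sp <- unique(ints$plant_species)
  bee_sp <- unique(ints$bee_species)
  spec <- ds$specimens
  plant_counts <- table(spec$species[spec$side == "plant"])
  for (s in plant_sp) {
    if (s %in% ds$immeasurable) next
    if (is.na(plant_counts[s]) || plant_counts[s] < 2) {
      issues <- add_issue(issues, "fatal",
        sprintf("plant species '%s' has <2 specimens and is not flagged immeasurable", s))
    }
  }
  if (sum(spec$side == "bee") < 2) {
    issues <- add_issue(issues, "fatal",
                        "fewer than 2 bee specimens for pooled regression")
  }
  structure(list(n_records = n_records,
                 n_bee_species = length(bee_sp),
                 n_plant_species = length(plant_sp),
                 issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("community: %d records, %d plant species, %d bee species\n",
              x$n_records, x$n_plant_species, x$n_bee_species))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$severity[i], x$issues$message[i]))
  } else cat("  no issues\n")
  invisible(x)
}

#' Write a quantitative network to disk
#'
#' Three plain-text formats: `matrix_csv` (plants as rows, bees as columns,
#' labels in the header row/column), `edgelist_tsv` (`plant_node, bee_node,
#' weight`, zero cells omitted) and `json` (matrix plus node metadata;
#' the only format that round-trips metadata).
#'
#' @param net a [quant_network()].
#' @param path output file path.
#' @param format one of `"matrix_csv"`, `"edgelist_tsv"`, `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(net, path,
                          format = c("matrix_csv", "edgelist_tsv", "json")) {
  format <- match.arg(format)
  m <- as_qmatrix(net)
  if (length(m) == 0) stop("empty network")
  if (format == "matrix_csv") {
    utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  } else if (format == "edgelist_tsv") {
    nz <- which(m > 0, arr.ind = TRUE)
    el <- data.frame(plant_node = rownames(m)[nz[, 1]],
                     bee_node = colnames(m)[nz[, 2]],
                     weight = m[nz], stringsAsFactors = FALSE)
    el <- el[order(nz[, 1], nz[, 2]), ]
    utils::write.table(el, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    obj <- list(plant_labels = rownames(m), bee_labels = colnames(m),
                matrix = unname(m))
    if (inherits(net, "quant_network")) {
      obj$plant_meta <- net$plant_meta
      obj$bee_meta <- net$bee_meta
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a quantitative network written by [write_network()]
#'
#' @param path file path.
#' @param format the format the file was written in.
#' @return a [quant_network()].
#' @export
read_network <- function(path,
                         format = c("matrix_csv", "edgelist_tsv", "json")) {
  format <- match.arg(format)
  if (format == "matrix_csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    quant_network(as.matrix(df))
  } else if (format == "edgelist_tsv") {
    el <- utils::read.delim(path, stringsAsFactors = FALSE)
    p <- unique(el$plant_node); b <- unique(el$bee_node)
    m <- matrix(0, length(p), length(b), dimnames = list(p, b))
    m[cbind(match(el$plant_node, p), match(el$bee_node, b))] <- el$weight
    quant_network(m)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- obj$matrix
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.numeric(m), nrow = length(obj$plant_labels),
                dimnames = list(obj$plant_labels, obj$bee_labels))
    pm <- if (!is.null(obj$plant_meta)) as.data.frame(obj$plant_meta)
    bm <- if (!is.null(obj$bee_meta)) as.data.frame(obj$bee_meta)
    quant_network(m, plant_meta = pm, bee_meta = bm)
  }
}

# --- issue-list plumbing ------------------------------------------------

new_issues <- function() {
  data.frame(severity = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_issue <- function(issues, severity, message) {
  rbind(issues, data.frame(severity = severity, message = message,
                           stringsAsFactors = FALSE))
}

remap_columns <- function(raw, req, column_map) {
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      if (column_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == column_map[[canon]]] <- canon
      }
    }
  }
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  raw
}
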