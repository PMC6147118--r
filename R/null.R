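#' Draw one fixed-margin contingency table (Patefield algorithm)
#'
#' Samples a count matrix with both marginal totals fixed, from the
#' multivariate hypergeometric law (the distribution conditioned on the
#' margins): rows are filled sequentially, each row's allocation drawn as
#' a multivariate hypergeometric from the remaining column pools.  This is
#' the distribution behind the classical `r2dtable` null model.
#'
#' Uses R's global random number generator; call `set.seed()` (or use
#' [null_distribution()], which seeds for you) for reproducibility.
#'
#' @param row_totals,col_totals non-negative integer margins with equal
#'   sums.
#' @return an integer matrix with exactly the requested margins.
#' @export
patefield_sample <- function(row_totals, col_totals) {
  r <- as.integer(round(row_totals)); c <- as.integer(round(col_totals))
  if (any(r < 0) || any(c < 0)) stop("margins must be non-negative")
  if (sum(r) != sum(c)) stop("row and column totals must have equal sums")
  P <- length(r); A <- length(c)
  out <- matrix(0L, P, A)
  pool <- c
  for (i in seq_len(P)) {
    need <- r[i]
    for (j in seq_len(A)) {
      if (need == 0L) break
      rest <- if (j < A) sum(pool[(j + 1):A]) else 0L
      x <- if (rest == 0L) need
           else as.integer(stats::rhyper(1, pool[j], rest, need))
      out[i, j] <- x
      pool[j] <- pool[j] - x
      need <- need - x
    }
  }
  out
}

#' Draw one marginal-conserving randomized matrix (nestedness nulls)
#'
#' Three weighted null models used for nestedness testing:
#' \describe{
#'   \item{CRT}{Conserve Row Totals: each row total is redistributed over
#'     the columns by a uniform multinomial.}
#'   \item{CCT}{Conserve Column Totals: symmetric, over rows.}
#'   \item{RCTA}{Row-Column Total Average: all `m` interactions are placed
#'     by one multinomial with cell probability proportional to
#'     `A_i/m + B_j/m`; only `m` is conserved exactly.}
#' }
#'
#' @param mat observed count matrix (or [quant_network()]).
#' @param model `"CRT"`, `"CCT"` or `"RCTA"`.
#' @return an integer matrix of the same dimensions.
#' @export
falcon_null_sample <- function(mat, model = c("CRT", "CCT", "RCTA")) {
  model <- match.arg(model)
  m <- as_qmatrix(mat)
  P <- nrow(m); A <- ncol(m)
  out <- switch(model,
    CRT = t(vapply(seq_len(P), function(i) {
      as.integer(stats::rmultinom(1, rowSums(m)[i], rep(1 / A, A)))
    }, integer(A))),
    CCT = vapply(seq_len(A), function(j) {
      as.integer(stats::rmultinom(1, colSums(m)[j], rep(1 / P, P)))
    }, integer(P)),
    RCTA = {
      tot <- sum(m)
      p <- outer(rowSums(m) / tot, colSums(m) / tot, "+") / (P + A)
      matrix(as.integer(stats::rmultinom(1, tot, as.vector(p))), P, A)
    })
  dimnames(out) <- dimnames(m)
  out
}

#' Null distribution of a metric under a randomization model
#'
#' Draws `n` randomized matrices under the chosen model and evaluates
#' `metric_fn` on each; samples where the metric fails (e.g. a zero
#' margin) are dropped and counted.
#'
#' @param net observed [quant_network()] or count matrix.
#' @param metric_fn function taking a count matrix and returning a number.
#' @param model `"r2dtable"` (fixed margins, Patefield), `"CRT"`, `"CCT"`
#'   or `"RCTA"`.
#' @param n ensemble size (default 1000).
#' @param seed integer seed; the ensemble is fully reproducible given
#'   `(seed, model, margins)`.  The caller's RNG state is preserved.
#' @return a list of class `null_ensemble`: `model`, `n`, `n_effective`,
#'   `seed`, `samples`, `null_mean`, `null_sd`.
#' @export
null_distribution <- function(net, metric_fn,
                              model = c("r2dtable", "CRT", "CCT", "RCTA"),
                              n = 1000, seed = NULL) {
  model <- match.arg(model)
  if (n < 2) stop("n must be >= 2")
  m <- as_qmatrix(net)
  rt <- rowSums(m); ct <- colSums(m)
  samples <- with_seed(seed, vapply(seq_len(n), function(i) {
    rm <- if (model == "r2dtable") patefield_sample(rt, ct)
          else falcon_null_sample(m, model)
    tryCatch(as.numeric(metric_fn(rm)), error = function(e) NA_real_)
  }, numeric(1)))
  eff <- samples[!is.na(samples)]
  structure(list(model = model, n = n, n_effective = length(eff),
                 n_dropped = n - length(eff), seed = seed, samples = eff,
                 null_mean = mean(eff), null_sd = stats::sd(eff)),
            class = "null_ensemble")
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' z-score and empirical p-value against a null ensemble
#'
#' The standard z is `(observed - null_mean) / null_sd`.  Some reports use
#' the reversed sign convention, where a positive z indicates an observed
#' value *below* the null mean; both are returned.  The two-sided p-value
#' comes from the empirical ranks with add-one smoothing:
#' `p = min(1, 2 * min(p_lower, p_upper))` with
#' `p_lower = (#{s <= obs} + 1) / (n + 1)`.
#'
#' @param observed observed metric value.
#' @param ensemble a `null_ensemble` (or numeric vector of null samples).
#' @return a list of class `significance_test`: `observed`, `null_mean`,
#'   `null_sd`, `n`, `z` (standard), `z_reversed`, `p_two_sided`.
#' @export
zscore_test <- function(observed, ensemble) {
  s <- if (inherits(ensemble, "null_ensemble")) ensemble$samples
       else as.numeric(ensemble)
  n <- length(s)
  mu <- mean(s); sdv <- stats::sd(s)
  z <- if (sdv > 0) (observed - mu) / sdv else NA_real_
  p_lo <- (sum(s <= observed) + 1) / (n + 1)
  p_hi <- (sum(s >= observed) + 1) / (n + 1)
  structure(list(observed = observed, null_mean = mu, null_sd = sdv,
                 n = n, z = z, z_reversed = if (is.na(z)) NA_real_ else -z,
                 p_two_sided = min(1, 2 * min(p_lo, p_hi))),
            class = "significance_test")
}

#' @export
print.significance_test <- function(x, ...) {
  cat(sprintf("observed %.4f vs null %.4f +/- %.4f (n = %d): z = %s, p = %.4g\n",
              x$observed, x$null_mean, x$null_sd, x$n,
              if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
              x$p_two_sided))
  invisible(x)
}

#' Nestedness significance under three marginal-conserving nulls
#'
#' Tests a nestedness metric (WNODF by default) against the CRT, CCT and
#' RCTA null models with an adaptive ensemble: the ensemble starts at
#' `start` draws and doubles until the empirical p-value changes by less
#' than `tol` between stages or `max_n` draws are reached, reducing
#' undersampling of the null distribution without a fixed oversized
#' ensemble.
#'
#' @param net observed [quant_network()] or count matrix, at least 2x2.
#' @param models subset of `c("CRT", "CCT", "RCTA")`.
#' @param metric_fn nestedness function, default [wnodf()].
#' @param start,max_n,tol adaptive-ensemble policy (defaults 500, 10000,
#'   0.005).
#' @param seed integer seed; per-model sub-seeds are derived from it.
#' @return named list (per model) of `significance_test`s, each with an
#'   `n_final` element appended.
#' @export
nestedness_significance <- function(net, models = c("CRT", "CCT", "RCTA"),
                                    metric_fn = wnodf, start = 500,
                                    max_n = 10000, tol = 0.005,
                                    seed = NULL) {
  m <- as_qmatrix(net)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 matrix")
  observed <- metric_fn(m)
  out <- list()
  for (k in seq_along(models)) {
    model <- models[k]
    sub_seed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
    samples <- numeric(0)
    n_next <- start
    p_prev <- NULL
    repeat {
      add <- null_distribution(m, metric_fn, model,
                               n = n_next - length(samples),
                               seed = if (is.null(sub_seed)) NULL
                                      else sub_seed + length(samples))
      samples <- c(samples, add$samples)
      p_now <- zscore_test(observed, samples)$p_two_sided
      if ((!is.null(p_prev) && abs(p_now - p_prev) < tol) ||
          length(samples) >= max_n) break
      p_prev <- p_now
      n_next <- min(max_n, 2 * n_next)
    }
    res <- zscore_test(observed, samples)
    res$n_final <- length(samples)
    res$model <- model
    out[[model]] <- res
  }
  out
}
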