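#' Bivariate LOESS smoother
#'
#' Locally weighted regression of a response on planar coordinates: for each
#' evaluation point the `q = ceiling(span * n)` nearest data points (ties at
#' the boundary distance included) receive tricube kernel weights
#' `(1 - (d/d_q)^3)^3`, and a weighted linear model in `(x, y)` -- kernel
#' times prior weights -- is solved; the prediction is the local fit at the
#' evaluation point.  Distances are raw Euclidean: both axes are assumed to
#' share units, as they do for the generated study regions.  Collinear
#' neighbourhoods fall back to a tiny ridge regulariser (1e-8 relative to
#' the local weight mass).
#'
#' @param coords n x 2 matrix of data locations.
#' @param response Numeric response vector of length n.
#' @param span Fraction of the data in each local neighbourhood, in (0, 1];
#'   the neighbourhood must contain at least 3 points.
#' @param weights Optional non-negative prior weights (default all 1).
#' @param eval_points m x 2 matrix of evaluation locations (default: the
#'   data locations).
#' @param hat `"none"` (default), `"diag"` (diagonal of the smoother
#'   operator; only defined when evaluating at the data points), or
#'   `"rows"` (the full m x n operator matrix, for small problems).
#' @return A list with `fitted` (length m), and depending on `hat`:
#'   `diag`, `trace`, or `rows`.
#' @examples
#' xy <- cbind(runif(50), runif(50))
#' z <- 1 + 2 * xy[, 1] - xy[, 2]
#' f <- loess2d(xy, z, span = 0.95)
#' max(abs(f$fitted - z))  # local linear reproduces planes
#' @export
loess2d <- function(coords, response, span, weights = NULL,
                    eval_points = NULL, hat = c("none", "diag", "rows")) {
  hat <- match.arg(hat)
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  stopifnot(length(response) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative, not all zero, one per data point")
  q <- span_to_q(span, n)
  at_data <- is.null(eval_points)
  if (at_data) eval_points <- coords else eval_points <- as_coord_matrix(eval_points)
  self_idx <- if (at_data) seq_len(n) - 1L else self_positions(coords, eval_points)
  pre <- loess2d_precompute(coords, eval_points, q, self_idx)
  if (hat == "rows") {
    rows <- loess2d_rows(pre, as.numeric(weights))
    return(list(fitted = as.numeric(rows %*% response), rows = rows, q = q))
  }
  ap <- loess2d_apply(pre, as.numeric(response), as.numeric(weights),
                      hat == "diag")
  out <- list(fitted = ap$fitted, q = q, n_ridge = ap$n_ridge)
  if (hat == "diag") {
    out$diag <- ap$diag
    out$trace <- sum(ap$diag)
  }
  out
}

#' Effective degrees of freedom of the LOESS smoother
#'
#' The trace of the n x n linear operator mapping responses to fitted
#' values at the data locations, for given span and prior weights.  This is
#' the effective-dimension term entering the AIC of the logistic GAM.
#'
#' @inheritParams loess2d
#' @return The trace, a real number between 3 (a single planar fit) and n.
#' @export
smoother_trace <- function(coords, span, weights = NULL) {
  loess2d(coords, rep(0, nrow(as_coord_matrix(coords))), span,
          weights = weights, hat = "diag")$trace
}

span_to_q <- function(span, n) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must be a single number in (0, 1]")
  q <- as.integer(ceiling(span * n))
  if (q < 3L)
    stop(sprintf("span %.3g gives a neighbourhood of %d < 3 points", span, q))
  q
}

# 0-based index of each eval point among the data points (exact coordinate
# match), or -1; used so operator diagonals are defined when evaluating at
# subject locations.
self_positions <- function(coords, eval_points) {
  key <- paste(coords[, 1], coords[, 2])
  pos <- match(paste(eval_points[, 1], eval_points[, 2]), key)
  ifelse(is.na(pos), -1L, pos - 1L)
}

# Neighbourhood cache: precomputed structures per span for a fixed dataset
# and a fixed probe set, reused across local-scoring iterations and
# permutation refits.
make_loess_cache <- function(coords, probe_points = NULL) {
  coords <- as_coord_matrix(coords)
  env <- new.env(parent = emptyenv())
  env$coords <- coords
  env$n <- nrow(coords)
  env$data_pre <- list()
  env$probe_pre <- list()
  env$probes <- if (!is.null(probe_points)) as_coord_matrix(probe_points)
  env
}

# Neighbourhoods depend on the span only through q, so cache entries are
# keyed by q: spans mapping to the same neighbourhood size share one
# structure (and hence give exactly identical fits).
cache_data_pre <- function(cache, span) {
  key <- as.character(span_to_q(span, cache$n))
  if (is.null(cache$data_pre[[key]])) {
    cache$data_pre[[key]] <- loess2d_precompute(
      cache$coords, cache$coords, as.integer(key), seq_len(cache$n) - 1L)
  }
  cache$data_pre[[key]]
}

cache_probe_pre <- function(cache, span) {
  if (is.null(cache$probes)) return(NULL)
  key <- as.character(span_to_q(span, cache$n))
  if (is.null(cache$probe_pre[[key]])) {
    cache$probe_pre[[key]] <- loess2d_precompute(
      cache$coords, cache$probes, as.integer(key),
      self_positions(cache$coords, cache$probes))
  }
  cache$probe_pre[[key]]
}
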