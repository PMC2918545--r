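#' Sample uniform point locations in a study region
#'
#' Locations are i.i.d. uniform over the region: directly for squares, by
#' rejection sampling from the bounding square for disks.
#'
#' @param region A `study_region`.
#' @param n Number of points.
#' @param seed Optional integer seed.
#' @return An n x 2 matrix of coordinates.
#' @export
sample_region_points <- function(region, n, seed = NULL) {
  stopifnot(inherits(region, "study_region"))
  n <- as.integer(n)
  if (n < 1) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  cx <- region$center[1]; cy <- region$center[2]; r <- region$radius
  if (region$shape == "square") {
    out <- cbind(x = runif(n, cx - r, cx + r), y = runif(n, cy - r, cy + r))
    return(out)
  }
  # disk: rejection from the bounding square (acceptance rate pi/4)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) / 0.7))
    px <- runif(m, -r, r); py <- runif(m, -r, r)
    keep <- px * px + py * py <= r * r
    k <- min(sum(keep), n - got)
    if (k > 0) {
      idx <- which(keep)[seq_len(k)]
      out[(got + 1):(got + k), ] <- cbind(px[idx] + cx, py[idx] + cy)
      got <- got + k
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' True log odds of disease under a simulation scenario
#'
#' Scenario 1: `logit(p) + log(OR)` inside the cluster disk, `logit(p)`
#' outside.  Scenario 2: `logit(p) + log(OR) * (1 - r/R)` where `r` is the
#' distance to the region centre and `R` the region radius.  Scenario 3:
#' `logit(p) + log(OR) * (1 - |x - cx|/h)` with `h` the half-side.  In all
#' scenarios the odds ratio compares the most-exposed location to the least
#' exposed (edge/outside), and `odds_ratio = 1` gives a flat surface.
#'
#' @param region A `study_region` consistent with `config$case_id`.
#' @param config A `scenario_config`.
#' @param points n x 2 matrix of locations inside the region.
#' @return Numeric vector of log odds.
#' @export
true_logodds <- function(region, config, points) {
  stopifnot(inherits(region, "study_region"),
            inherits(config, "scenario_config"))
  points <- as_coord_matrix(points)
  qlogis(config$p_unexposed) +
    log(config$odds_ratio) * exposure_score(region, config$case_id, points)
}

#' Exposure score of locations under a scenario
#'
#' The covariate `u` in `[0, 1]` multiplying `log(OR)` in the true log odds:
#' the cluster indicator (scenario 1), `1 - r/R` (scenario 2), or
#' `1 - |x - cx|/h` (scenario 3).  This is also the covariate used by the
#' non-spatial reference tests.
#'
#' @param region A `study_region`.
#' @param case_id Scenario identifier.
#' @param points n x 2 matrix of locations.
#' @return Numeric vector in `[0, 1]`.
#' @export
exposure_score <- function(region, case_id, points) {
  points <- as_coord_matrix(points)
  cx <- region$center[1]; cy <- region$center[2]
  switch(as.integer(case_id),
         {
           if (region$cluster_radius <= 0)
             stop("scenario 1 needs a region with an embedded cluster disk")
           d <- sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)
           as.numeric(d <= region$cluster_radius)
         },
         {
           d <- sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)
           1 - d / region$radius
         },
         1 - abs(points[, 1] - cx) / region$radius,
         stop("case_id must be 1, 2 or 3"))
}

#' Generate a synthetic case-control dataset
#'
#' Locations are sampled uniformly over the scenario's study region and
#' outcomes are Bernoulli with probabilities given by [true_logodds()].
#' The number of subjects inside the scenario-1 cluster is therefore
#' binomial around 15% of `n_subjects`, not fixed.
#'
#' @param config A `scenario_config`; its `seed`, when set, makes the
#'   dataset reproducible in isolation.
#' @param region Study region; defaults to the scenario convention of
#'   [case_region()].
#' @return A `point_dataset`.  Degenerate outcome vectors (all 0 or all 1)
#'   are flagged, not rejected; downstream tests refuse them.
#' @export
generate_dataset <- function(config, region = case_region(config$case_id)) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  coords <- sample_region_points(region, config$n_subjects)
  eta <- true_logodds(region, config, coords)
  y <- rbinom(config$n_subjects, 1L, plogis(eta))
  point_dataset(coords, y, region)
}

#' Derive the seed of one dataset in a simulation stream
#'
#' Simulation studies draw dataset `i` with seed `root_seed + i`, so any
#' single dataset can be regenerated in isolation.
#'
#' @param root_seed Integer root seed of the study.
#' @param i Dataset index (1-based).
#' @return Integer seed.
#' @export
dataset_seed <- function(root_seed, i) {
  s <- as.integer(root_seed) + as.integer(i)
  if (is.na(s)) stop("seed overflow; use a smaller root seed")
  s
}
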