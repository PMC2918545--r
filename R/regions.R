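#' Study-region geometry
#'
#' A study region is the sampling window for subject locations: either a
#' disk or an axis-aligned square, optionally carrying the geometry of an
#' embedded exposure source (a cluster disk, the centre point, or a vertical
#' line through the centre).  All downstream statistics are invariant to
#' rescaling the region, so the absolute units are a convention.
#'
#' @param radius Radius of the disk (coordinate units).
#' @param center Centre of the region, length-2 numeric.
#' @param cluster_radius Radius of an embedded disk of constant elevated or
#'   reduced risk; `0` means no cluster.
#' @param source One of `"cluster_disk"`, `"center_point"`,
#'   `"vertical_line"`, `"none"`: the exposure-source geometry the region
#'   carries for sensitivity evaluation.
#' @return An object of class `study_region`.
#' @examples
#' r <- region_disk(sqrt(0.15), cluster_radius = 0.15)
#' r
#' @export
region_disk <- function(radius, center = c(0, 0), cluster_radius = 0,
                        source = if (cluster_radius > 0) "cluster_disk" else "none") {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            length(center) == 2L, cluster_radius >= 0)
  if (cluster_radius >= radius)
    stop("cluster_radius must be smaller than the region radius")
  structure(list(shape = "disk", center = as.numeric(center), radius = radius,
                 cluster_radius = cluster_radius,
                 source = match.arg(source, c("cluster_disk", "center_point",
                                              "vertical_line", "none"))),
            class = "study_region")
}

#' @rdname region_disk
#' @param halfside Half the side length of the square.
#' @export
region_square <- function(halfside = 0.5, center = c(0.5, 0.5),
                          source = "none") {
  stopifnot(is.numeric(halfside), length(halfside) == 1L, halfside > 0,
            length(center) == 2L)
  structure(list(shape = "square", center = as.numeric(center),
                 radius = halfside, cluster_radius = 0,
                 source = match.arg(source, c("cluster_disk", "center_point",
                                              "vertical_line", "none"))),
            class = "study_region")
}

#' @export
print.study_region <- function(x, ...) {
  cat(sprintf("Study region: %s, center (%g, %g), %s %g\n", x$shape,
              x$center[1], x$center[2],
              if (x$shape == "disk") "radius" else "half-side", x$radius))
  if (x$cluster_radius > 0)
    cat(sprintf("  embedded cluster disk of radius %g (%.1f%% of area)\n",
                x$cluster_radius, 100 * (x$cluster_radius / x$radius)^2))
  if (x$source != "none") cat("  exposure source:", x$source, "\n")
  invisible(x)
}

#' Default study region for each simulation scenario
#'
#' Scenario 1 and 2 use a disk of radius `sqrt(0.15)` centred at the origin;
#' for scenario 1 it embeds a central cluster disk of radius 0.15, which
#' covers 15% of the region area.  Scenario 3 uses the unit square with a
#' vertical source line through `x = 0.5`.  These constants fix the
#' coordinate convention; every test statistic in the package is invariant
#' to rescaling them.
#'
#' @param case_id Scenario identifier, 1, 2 or 3.
#' @return A `study_region`.
#' @export
case_region <- function(case_id) {
  case_id <- as.integer(case_id)
  switch(case_id,
         region_disk(sqrt(0.15), cluster_radius = 0.15,
                     source = "cluster_disk"),
         region_disk(sqrt(0.15), source = "center_point"),
         region_square(0.5, c(0.5, 0.5), source = "vertical_line"),
         stop("case_id must be 1, 2 or 3"))
}

#' Is a set of points inside a region?
#'
#' @param region A `study_region`.
#' @param points An n x 2 matrix of coordinates.
#' @param tol Boundary tolerance, relative to the region size.
#' @return Logical vector of length n.
#' @export
in_region <- function(region, points, tol = 1e-8) {
  points <- as_coord_matrix(points)
  eps <- tol * region$radius
  if (region$shape == "disk") {
    d <- sqrt((points[, 1] - region$center[1])^2 +
              (points[, 2] - region$center[2])^2)
    d <= region$radius + eps
  } else {
    abs(points[, 1] - region$center[1]) <= region$radius + eps &
      abs(points[, 2] - region$center[2]) <= region$radius + eps
  }
}

as_coord_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  points
}

#' Simulation scenario configuration
#'
#' One simulation condition of the synthetic-data generator: the scenario
#' geometry (`case_id`), the disease probability for the least-exposed
#' subjects (`p_unexposed`), the odds ratio comparing the most exposed to
#' the least exposed subjects, and the number of subjects per dataset.
#'
#' @param case_id 1 (central circular cluster of constant risk in a disk),
#'   2 (log odds linear in proximity to the disk centre), or 3 (log odds
#'   linear in proximity to the vertical centre line of the unit square).
#' @param p_unexposed Disease probability outside the cluster (scenario 1)
#'   or at the region edge (scenarios 2 and 3); in (0, 1).
#' @param odds_ratio Odds ratio for the most-exposed subjects relative to
#'   the least exposed; `1` is the null of no spatial variation.
#' @param n_subjects Subjects per dataset (the replication default is 1000).
#' @param seed Optional integer seed fixing the dataset.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(case_id, p_unexposed, odds_ratio,
                            n_subjects = 1000L, seed = NULL) {
  case_id <- as.integer(case_id)
  stopifnot(case_id %in% 1:3,
            is.numeric(p_unexposed), p_unexposed > 0, p_unexposed < 1,
            is.numeric(odds_ratio), odds_ratio > 0,
            n_subjects >= 2)
  structure(list(case_id = case_id, p_unexposed = p_unexposed,
                 odds_ratio = odds_ratio, n_subjects = as.integer(n_subjects),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %d: p_unexposed = %g, OR = %g, n = %d%s\n",
              x$case_id, x$p_unexposed, x$odds_ratio, x$n_subjects,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Case-control point dataset
#'
#' The container consumed by every test in the package: subject coordinates,
#' binary outcomes and the study region they were sampled from.  Datasets in
#' which all outcomes are equal are flagged `degenerate`; the hypothesis
#' tests refuse such input.
#'
#' @param coords n x 2 numeric matrix of locations.
#' @param outcome length-n vector of 0/1 outcomes.
#' @param region A `study_region` containing all points.
#' @return An object of class `point_dataset`.
#' @export
point_dataset <- function(coords, outcome, region) {
  coords <- as_coord_matrix(coords)
  outcome <- as.integer(outcome)
  stopifnot(nrow(coords) == length(outcome))
  if (!all(outcome %in% c(0L, 1L))) {
    bad <- which(!(outcome %in% c(0L, 1L)))[1]
    stop(sprintf("outcome must be 0/1; offending row %d has value %s",
                 bad, outcome[bad]))
  }
  if (!inherits(region, "study_region")) stop("region must be a study_region")
  inside <- in_region(region, coords)
  if (!all(inside))
    stop(sprintf("%d point(s) fall outside the study region (first: row %d)",
                 sum(!inside), which(!inside)[1]))
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, outcome = outcome, region = region,
                 degenerate = all(outcome == 0L) || all(outcome == 1L)),
            class = "point_dataset")
}

#' @export
print.point_dataset <- function(x, ...) {
  cat(sprintf("Point dataset: %d subjects, %d cases (%.1f%%), %s region%s\n",
              length(x$outcome), sum(x$outcome),
              100 * mean(x$outcome), x$region$shape,
              if (x$degenerate) " [degenerate outcomes]" else ""))
  invisible(x)
}

check_nondegenerate <- function(data) {
  if (!inherits(data, "point_dataset")) stop("expected a point_dataset")
  if (data$degenerate)
    stop("dataset has degenerate outcomes (all 0 or all 1)")
  invisible(data)
}
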