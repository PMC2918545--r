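#' Wald confidence interval for a proportion
#'
#' `p_hat +/- 1.96 sqrt(p_hat (1 - p_hat) / n)`, clipped to `[0, 1]`; the
#' interval attached to every simulated power and sensitivity estimate.
#'
#' @param p_hat Estimated proportion.
#' @param n Number of replicates.
#' @return Length-2 vector `c(low, high)`.
#' @examples
#' wald_ci(0.923, 1000)  # 0.906 0.940
#' @export
wald_ci <- function(p_hat, n) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1)
  me <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  c(max(0, p_hat - me), min(1, p_hat + me))
}

#' Configuration of a simulation study
#'
#' The full grid of scenarios (cases x baseline probabilities x odds
#' ratios), the methods compared, and the replication sizes.  The paper
#' replication preset is 1000 datasets of 1000 subjects with 999
#' permutations / Monte Carlo replicates; that preset takes hours per
#' scenario on one CPU, so reduced presets (the default here) are
#' first-class and their Monte Carlo error is reported with every
#' estimate.
#'
#' @param cases Scenario ids, subset of 1:3.
#' @param p_unexposed Baseline probabilities.
#' @param odds_ratios Odds ratios (1 gives type I error rows).
#' @param methods Subset of `c("cpt", "fmspt3", "fmspt5", "upt", "scan")`.
#' @param n_datasets Datasets per scenario.
#' @param n_subjects Subjects per dataset.
#' @param n_perm Permutations for the GAM tests.
#' @param n_mc Monte Carlo replicates for the scan.
#' @param grid Span grid for AIC selection.
#' @param root_seed Root seed; dataset `i` of scenario `s` is regenerated
#'   exactly from `root_seed` alone.
#' @param sensitivity Whether to evaluate source-detection sensitivity
#'   (requires point-wise predictions; costlier for the GAM tests).
#' @return A list of class `study_config`.
#' @export
study_config <- function(cases = 1:3, p_unexposed = c(0.05, 0.2),
                         odds_ratios = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5),
                         methods = c("cpt", "fmspt3", "fmspt5", "scan"),
                         n_datasets = 100L, n_subjects = 1000L,
                         n_perm = 99L, n_mc = 99L, grid = span_grid(),
                         root_seed = 1L, sensitivity = TRUE) {
  methods <- match.arg(methods, c("cpt", "fmspt3", "fmspt5", "upt", "scan"),
                       several.ok = TRUE)
  structure(list(cases = as.integer(cases), p_unexposed = p_unexposed,
                 odds_ratios = odds_ratios, methods = methods,
                 n_datasets = as.integer(n_datasets),
                 n_subjects = as.integer(n_subjects),
                 n_perm = as.integer(n_perm), n_mc = as.integer(n_mc),
                 grid = grid, root_seed = as.integer(root_seed),
                 sensitivity = isTRUE(sensitivity)),
            class = "study_config")
}

#' Probe points along the vertical source line of scenario 3
#'
#' @param region The scenario-3 square region.
#' @param n Number of equally spaced probes (101 in the replication).
#' @return An n x 2 matrix on the line `x = cx`.
#' @export
source_line_probes <- function(region, n = 101L) {
  cbind(x = rep(region$center[1], n),
        y = seq(region$center[2] - region$radius,
                region$center[2] + region$radius, length.out = n))
}

# Probe set used for sensitivity evaluation of a scenario.
scenario_probes <- function(case_id, region, data) {
  switch(as.integer(case_id),
         data$coords,
         matrix(region$center, 1, 2, dimnames = list(NULL, c("x", "y"))),
         source_line_probes(region))
}

#' Proportion of the true cluster flagged in the effect direction
#' (scenario 1 sensitivity)
#'
#' For a GAM permutation test with point-wise predictions at the subject
#' locations: the fraction of subjects inside the true cluster disk whose
#' flag matches the effect direction (hot for OR > 1, cold for OR < 1),
#' taking the union over spans for multi-span tests.  For a scan test: the
#' fraction of true-cluster subjects belonging to a significant most
#' likely cluster.  Sensitivity is conditional on global rejection;
#' `NA` is returned when the test did not reject.
#'
#' @param result A `gam_perm_test` (probes = subject locations) or
#'   `scan_test`.
#' @param data The `point_dataset` the test was run on.
#' @param region Study region carrying the true cluster disk.
#' @param direction `"high"` for OR > 1, `"low"` for OR < 1.
#' @return Proportion in `[0, 1]`, or `NA` if the global null was not
#'   rejected.
#' @export
case1_sensitivity <- function(result, data, region,
                              direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (region$cluster_radius <= 0) stop("region has no true cluster disk")
  d <- sqrt((data$coords[, 1] - region$center[1])^2 +
            (data$coords[, 2] - region$center[2])^2)
  in_cluster <- d <= region$cluster_radius
  if (!any(in_cluster)) return(NA_real_)
  if (inherits(result, "scan_test")) {
    if (!result$reject) return(NA_real_)
    member <- rep(FALSE, length(data$outcome))
    member[result$mlc$members] <- TRUE
    return(mean(member[in_cluster]))
  }
  if (!inherits(result, "gam_perm_test")) stop("unsupported result object")
  if (!result$reject) return(NA_real_)
  if (is.null(result$pointwise) ||
      nrow(result$probes) != length(data$outcome))
    stop("test must carry point-wise flags at the subject locations")
  mean(flag_union(result, direction)[in_cluster])
}

#' Was the exposure source location detected? (scenario 2 sensitivity)
#'
#' For a GAM permutation test: the predicted log odds at the region centre
#' falls in the flagged tail matching the effect direction, at the test's
#' span (CPT) or at one span at least (FMSPT).  For a scan test: the
#' region centre lies inside a significant most likely cluster.
#' Conditional on global rejection (`NA` otherwise).
#'
#' @inheritParams case1_sensitivity
#' @return `TRUE`/`FALSE`, or `NA` if the global null was not rejected.
#' @export
case2_sensitivity <- function(result, data, region,
                              direction = c("high", "low")) {
  direction <- match.arg(direction)
  ctr <- region$center
  if (inherits(result, "scan_test")) {
    if (!result$reject) return(NA)
    cc <- data$coords[result$mlc$center_index, ]
    return(sqrt(sum((cc - ctr)^2)) <= result$mlc$radius)
  }
  if (!inherits(result, "gam_perm_test")) stop("unsupported result object")
  if (!result$reject) return(NA)
  if (is.null(result$pointwise)) stop("test carries no point-wise flags")
  at_ctr <- which(result$probes[, 1] == ctr[1] & result$probes[, 2] == ctr[2])
  if (length(at_ctr) != 1)
    stop("probe set must contain the region centre exactly once")
  flag_union(result, direction)[at_ctr]
}

#' Proportion of the vertical source line detected (scenario 3 sensitivity)
#'
#' For a GAM permutation test with probes along the source line: the
#' fraction of line probes flagged in the effect direction (union over
#' spans for the FMSPT).  For a scan test: the fraction of line probes
#' falling inside a significant most likely cluster.  Conditional on
#' global rejection (`NA` otherwise).
#'
#' @inheritParams case1_sensitivity
#' @param probe_line m x 2 matrix of points on the source line; defaults
#'   to the probes stored in a GAM result, or 101 equally spaced points
#'   for a scan result.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
case3_sensitivity <- function(result, data, region, probe_line = NULL,
                              direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (inherits(result, "scan_test")) {
    if (!result$reject) return(NA_real_)
    if (is.null(probe_line)) probe_line <- source_line_probes(region)
    cc <- data$coords[result$mlc$center_index, ]
    d <- sqrt((probe_line[, 1] - cc[1])^2 + (probe_line[, 2] - cc[2])^2)
    return(mean(d <= result$mlc$radius))
  }
  if (!inherits(result, "gam_perm_test")) stop("unsupported result object")
  if (!result$reject) return(NA_real_)
  if (is.null(result$pointwise)) stop("test carries no point-wise flags")
  mean(flag_union(result, direction))
}

#' Run a power / type I error / sensitivity simulation study
#'
#' For every scenario in the configuration grid, generates datasets,
#' applies each method at its own significance cutoff (CPT 0.025, FMSPT
#' 0.05/k, UPT and scan 0.05), and records rejection, the selected span or
#' cluster radius, and -- when requested -- the scenario-specific
#' source-detection sensitivity, which is defined only over datasets where
#' the global null was rejected.
#'
#' @param config A `study_config`.
#' @param verbose Print progress per scenario.
#' @return A list of class `power_study`: `results` (one row per dataset x
#'   method), `power` (rejection rates with Wald intervals), `sensitivity`
#'   (summaries over rejected datasets), and the `config`.
#' @export
run_power_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  scen <- expand.grid(case_id = config$cases, p0 = config$p_unexposed,
                      OR = config$odds_ratios, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (s in seq_len(nrow(scen))) {
    case_id <- scen$case_id[s]; p0 <- scen$p0[s]; OR <- scen$OR[s]
    region <- case_region(case_id)
    direction <- if (OR >= 1) "high" else "low"
    if (verbose)
      message(sprintf("scenario %d/%d: case %d p0=%g OR=%g", s, nrow(scen),
                      case_id, p0, OR))
    for (i in seq_len(config$n_datasets)) {
      seed_i <- dataset_seed(config$root_seed,
                             (s - 1L) * config$n_datasets + i)
      cfg <- scenario_config(case_id, p0, OR, config$n_subjects,
                             seed = seed_i)
      dat <- generate_dataset(cfg, region)
      if (dat$degenerate) next
      probes <- if (config$sensitivity)
        scenario_probes(case_id, region, dat)
      for (method in config$methods) {
        res <- tryCatch(
          run_one_method(method, dat, config, probes),
          error = function(e) NULL)
        if (is.null(res)) next
        sens <- NA_real_
        if (config$sensitivity && OR != 1) {
          sens <- tryCatch(switch(
            as.character(case_id),
            "1" = case1_sensitivity(res$fit, dat, region, direction),
            "2" = as.numeric(case2_sensitivity(res$fit, dat, region,
                                               direction)),
            "3" = case3_sensitivity(res$fit, dat, region,
                                    direction = direction)),
            error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case_id, p0 = p0, OR = OR, dataset = i,
          seed = seed_i, method = method, reject = res$reject,
          p_value = res$p, chosen_span = res$span, radius = res$radius,
          sensitivity = sens)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(config = config, results = results,
                 power = summarize_power(results),
                 sensitivity = summarize_sensitivity(results)),
            class = "power_study")
}

run_one_method <- function(method, dat, config, probes) {
  switch(method,
    cpt = {
      r <- cpt(dat, n_perm = config$n_perm, grid = config$grid,
               probes = probes)
      list(fit = r, reject = r$reject, p = min(r$p_value),
           span = r$chosen_span, radius = NA_real_)
    },
    fmspt3 = {
      r <- fmspt(dat, spans = c(0.1, 0.5, 0.9), n_perm = config$n_perm,
                 probes = probes)
      list(fit = r, reject = r$reject, p = min(r$p_value),
           span = NA_real_, radius = NA_real_)
    },
    fmspt5 = {
      r <- fmspt(dat, spans = c(0.1, 0.3, 0.5, 0.7, 0.9),
                 n_perm = config$n_perm, probes = probes)
      list(fit = r, reject = r$reject, p = min(r$p_value),
           span = NA_real_, radius = NA_real_)
    },
    upt = {
      r <- upt(dat, n_perm = config$n_perm, grid = config$grid)
      list(fit = r, reject = r$reject, p = min(r$p_value),
           span = r$chosen_span, radius = NA_real_)
    },
    scan = {
      r <- scan_test(dat, n_mc = config$n_mc)
      list(fit = r, reject = r$reject, p = r$p_value, span = NA_real_,
           radius = if (r$reject) r$mlc$radius else NA_real_)
    },
    stop("unknown method: ", method))
}

summarize_power <- function(results) {
  agg <- aggregate(reject ~ case_id + p0 + OR + method, data = results,
                   FUN = function(x) c(rate = mean(x), n = length(x)))
  out <- data.frame(agg[1:4], power = agg$reject[, "rate"],
                    n_effective = agg$reject[, "n"])
  ci <- t(mapply(wald_ci, out$power, out$n_effective))
  out$ci_low <- ci[, 1]
  out$ci_high <- ci[, 2]
  out[order(out$case_id, out$p0, out$OR, out$method), ]
}

summarize_sensitivity <- function(results) {
  keep <- results$OR != 1 & !is.na(results$sensitivity)
  if (!any(keep)) return(NULL)
  r <- results[keep, ]
  agg <- aggregate(sensitivity ~ case_id + p0 + OR + method, data = r,
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  out <- data.frame(agg[1:4], mean = agg$sensitivity[, "mean"],
                    sd = agg$sensitivity[, "sd"],
                    n_rejected = agg$sensitivity[, "n"])
  ci <- t(mapply(wald_ci, pmin(pmax(out$mean, 0), 1), out$n_rejected))
  out$ci_low <- ci[, 1]
  out$ci_high <- ci[, 2]
  out[order(out$case_id, out$p0, out$OR, out$method), ]
}

#' Span- and radius-distribution diagnostics of a study
#'
#' Summaries of the CPT-selected span and of the radius of significant
#' most-likely clusters, per scenario.  Radii are reported in the
#' package's own coordinate convention (disk radius `sqrt(0.15)`, unit
#' square) and are diagnostics, not quantities with an absolute scale.
#'
#' @param study A `power_study`.
#' @return A data frame of per-scenario summaries.
#' @export
study_diagnostics <- function(study) {
  r <- study$results
  out <- list()
  sp <- r[r$method == "cpt" & !is.na(r$chosen_span), ]
  if (nrow(sp) > 0) {
    agg <- aggregate(chosen_span ~ case_id + p0 + OR, data = sp,
                     FUN = function(x) c(mean = mean(x), sd = sd(x),
                                         frac_large = mean(x > 0.8)))
    out$span <- data.frame(agg[1:3], what = "cpt_span",
                           mean = agg$chosen_span[, "mean"],
                           sd = agg$chosen_span[, "sd"],
                           frac_large = agg$chosen_span[, "frac_large"])
  }
  rad <- r[r$method == "scan" & !is.na(r$radius), ]
  if (nrow(rad) > 0) {
    agg <- aggregate(radius ~ case_id + p0 + OR, data = rad,
                     FUN = function(x) c(mean = mean(x), sd = sd(x),
                                         min = min(x), max = max(x)))
    out$radius <- data.frame(agg[1:3], what = "mlc_radius",
                             mean = agg$radius[, "mean"],
                             sd = agg$radius[, "sd"],
                             min = agg$radius[, "min"],
                             max = agg$radius[, "max"])
  }
  out
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf(
    "Simulation study: %d scenario(s) x %d dataset(s), methods: %s\n",
    nrow(unique(x$results[c("case_id", "p0", "OR")])),
    x$config$n_datasets, paste(x$config$methods, collapse = ", ")))
  cat("\nRejection rates:\n")
  print(x$power, row.names = FALSE, digits = 3)
  if (!is.null(x$sensitivity)) {
    cat("\nSource-detection sensitivity (rejected datasets only):\n")
    print(x$sensitivity, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
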