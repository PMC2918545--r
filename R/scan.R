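#' Bernoulli log-likelihood ratio of a circular zone
#'
#' With `p = c_z/n_z` the case fraction inside the zone and
#' `q = (C - c_z)/(N - n_z)` outside, the statistic is the log likelihood
#' of the two-rate Bernoulli model minus that of the single-rate null,
#' `0 * log(0)` taken as 0.  The value is returned only when the zone rate
#' deviates in the requested direction (`p > q` for `"high"`, `p < q` for
#' `"low"`); otherwise 0.
#'
#' @param c_z,n_z Cases and subjects inside the zone.
#' @param C,N Total cases and subjects.
#' @param direction `"high"` or `"low"`.
#' @return The log-likelihood ratio (non-negative).
#' @export
bernoulli_llr <- function(c_z, n_z, C, N, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (n_z < 1 || n_z > N || c_z < 0 || c_z > min(n_z, C) || C < 0 || C > N ||
      (C - c_z) > (N - n_z))
    stop("inconsistent zone/total counts")
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  lbin <- function(c, n) xlogx(c) + xlogx(n - c) - xlogx(n)
  p_in <- c_z / n_z
  p_out <- (C - c_z) / (N - n_z)
  if ((direction == "high" && !(p_in > p_out)) ||
      (direction == "low" && !(p_in < p_out))) return(0)
  max(0, lbin(c_z, n_z) + lbin(C - c_z, N - n_z) - lbin(C, N))
}

#' Most likely cluster of the circular Bernoulli scan
#'
#' Scans all circular zones -- for every subject as centre, the nested sets
#' of its nearest neighbours up to half the study population, with tied
#' distances entering together -- and returns the zone maximising the
#' Bernoulli log-likelihood ratio over the allowed directions.  Ties are
#' broken toward the smaller zone, then the smaller centre index.  The zone
#' radius is the distance from the centre to its farthest member.
#'
#' @param data A `point_dataset`.
#' @param directions Character subset of `c("high", "low")`; both by
#'   default, so clusters of reduced risk are also detected.
#' @return A list of class `scan_zone`: `center_index`, `radius`, `n_z`,
#'   `c_z`, `direction`, `llr`, `members`.
#' @export
most_likely_cluster <- function(data, directions = c("high", "low")) {
  check_nondegenerate(data)
  directions <- match.arg(directions, several.ok = TRUE)
  res <- scan_bernoulli_cpp(data$coords, data$outcome, 0L,
                            "high" %in% directions, "low" %in% directions)
  structure(res[c("center_index", "radius", "n_z", "c_z", "direction",
                  "llr", "members")], class = "scan_zone")
}

#' @export
print.scan_zone <- function(x, ...) {
  if (x$n_z == 0) {
    cat("No zone deviates from the overall rate (llr 0)\n")
    return(invisible(x))
  }
  cat(sprintf("Most likely cluster: %s-rate zone of %d subjects (%d cases)\n",
              x$direction, x$n_z, x$c_z))
  cat(sprintf("  centred at subject %d, radius %.4g, llr %.4f\n",
              x$center_index, x$radius, x$llr))
  invisible(x)
}

#' Circular Bernoulli spatial scan test
#'
#' Computes the most likely cluster and its Monte Carlo p-value: the
#' observed maximum log-likelihood ratio is ranked against the maxima of
#' `n_mc` random relabellings of the outcomes over the fixed locations
#' (case count preserved), `p = (1 + #{replicate >= observed})/(n_mc + 1)`.
#'
#' @inheritParams most_likely_cluster
#' @param n_mc Number of Monte Carlo replicates (999 in the replication
#'   preset; the minimal attainable p-value is `1/(n_mc + 1)`).
#' @param alpha Significance level for the `reject` field.
#' @param seed Optional integer seed.
#' @return A list of class `scan_test`: the `mlc` (a `scan_zone`),
#'   `p_value`, `n_mc`, `reject`.
#' @export
scan_test <- function(data, n_mc = 999L, directions = c("high", "low"),
                      alpha = 0.05, seed = NULL) {
  check_nondegenerate(data)
  directions <- match.arg(directions, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  res <- scan_bernoulli_cpp(data$coords, data$outcome, as.integer(n_mc),
                            "high" %in% directions, "low" %in% directions)
  p <- (1 + res$n_ge) / (n_mc + 1)
  structure(list(
    mlc = structure(res[c("center_index", "radius", "n_z", "c_z",
                          "direction", "llr", "members")],
                    class = "scan_zone"),
    p_value = p, n_mc = as.integer(n_mc), alpha = alpha,
    reject = p <= alpha, n_cases = res$n_cases,
    directions = directions), class = "scan_test", data = data)
}

#' @export
print.scan_test <- function(x, ...) {
  cat(sprintf("Bernoulli spatial scan (%s), %d Monte Carlo replicates\n",
              paste(x$directions, collapse = "+"), x$n_mc))
  print(x$mlc)
  cat(sprintf("  p = %.4g: null %s at alpha %.3g\n", x$p_value,
              if (x$reject) "REJECTED" else "not rejected", x$alpha))
  invisible(x)
}

#' Plot a scan result
#'
#' Subject locations (cases filled) with the most likely cluster circle.
#'
#' @param x A `scan_test`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scan_test <- function(x, ...) {
  stop_if_no_data <- function(d) if (is.null(d)) stop("scan_test carries no data")
  dat <- attr(x, "data")
  stop_if_no_data(dat)
  plot(dat$coords, asp = 1, pch = ifelse(dat$outcome == 1, 16, 1),
       cex = 0.5, xlab = "x", ylab = "y", ...)
  ctr <- dat$coords[x$mlc$center_index, ]
  symbols(ctr[1], ctr[2], circles = x$mlc$radius, inches = FALSE,
          add = TRUE, lwd = 2)
  invisible(x)
}
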