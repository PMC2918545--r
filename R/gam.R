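#' Intercept-only binomial deviance
#'
#' Deviance of the model with no spatial term: `-2 [C log(C/N) +
#' (N - C) log(1 - C/N)]` for `C` cases among `N` subjects.  This is the
#' reference against which the difference-in-deviance statistic is formed.
#'
#' @param data A `point_dataset` with both cases and controls.
#' @return The null deviance.
#' @export
null_deviance <- function(data) {
  check_nondegenerate(data)
  C <- sum(data$outcome); N <- length(data$outcome)
  p <- C / N
  -2 * (C * log(p) + (N - C) * log1p(-p))
}

# Local-scoring core on a raw outcome vector, given precomputed
# neighbourhoods.  Fisher scoring for the binomial GAM with a single
# bivariate smooth: the LOESS surface absorbs the intercept, so no
# backfitting loop is needed.
fit_gam_core <- function(y, data_pre, max_iter = 50L, tol = 1e-8,
                         prob_clip = 1e-10, want_edf = TRUE,
                         mu_init = NULL) {
  mu <- if (is.null(mu_init)) (y + mean(y)) / 2 else mu_init
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  z <- w <- NULL
  ap <- NULL
  repeat {
    iter <- iter + 1L
    eta_w <- qlogis(mu)
    w <- mu * (1 - mu)
    z <- eta_w + (y - mu) / w
    ap <- loess2d_apply(data_pre, z, w, want_edf)
    eta <- ap$fitted
    mu <- pmin(pmax(plogis(eta), prob_clip), 1 - prob_clip)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev_old) + 0.1)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    dev_old <- dev
  }
  list(eta = ap$fitted, mu = mu, deviance = dev,
       edf = if (want_edf) sum(ap$diag) else NA_real_,
       converged = converged, n_iter = iter, z = z, w = w)
}

# Batched local scoring: one binomial GAM per column of Y, all sharing the
# same coordinates/span, iterated in lockstep so the neighbourhood stream
# is traversed once per iteration for the whole batch.  Converged columns
# drop out of the active set.  Returns per-column deviances and the final
# working response/weights (for probe-point prediction).
fit_gam_core_multi <- function(Y, data_pre, max_iter = 50L, tol = 1e-8,
                               prob_clip = 1e-10) {
  n <- nrow(Y)
  B <- ncol(Y)
  mu <- (Y + matrix(colMeans(Y), n, B, byrow = TRUE)) / 2
  dev <- rep(NA_real_, B)
  dev_old <- rep(Inf, B)
  conv <- failed <- rep(FALSE, B)
  n_iter <- rep(0L, B)
  Zout <- Wout <- matrix(NA_real_, n, B)
  active <- rep(TRUE, B)
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    id <- which(active)
    Ya <- Y[, id, drop = FALSE]
    mua <- mu[, id, drop = FALSE]
    W <- mua * (1 - mua)
    Zw <- qlogis(mua) + (Ya - mua) / W
    ft <- loess2d_apply_multi(data_pre, t(Zw), t(W))$fitted
    mun <- pmin(pmax(plogis(ft), prob_clip), 1 - prob_clip)
    dv <- -2 * colSums(Ya * log(mun) + (1 - Ya) * log1p(-mun))
    Zout[, id] <- Zw
    Wout[, id] <- W
    mu[, id] <- mun
    n_iter[id] <- it
    bad <- !is.finite(dv)
    done <- bad | abs(dv - dev_old[id]) < tol * (abs(dev_old[id]) + 0.1)
    dev[id] <- dv
    dev_old[id] <- dv
    conv[id[done & !bad]] <- TRUE
    failed[id[bad]] <- TRUE
    active[id[done]] <- FALSE
  }
  list(deviance = dev, converged = conv, failed = failed, n_iter = n_iter,
       Z = Zout, W = Wout)
}

#' Fit a logistic GAM with a bivariate LOESS smooth of location
#'
#' Fits `logit P(Y = 1) = f(x, y)` by local scoring (iteratively reweighted
#' LOESS smoothing of the binomial working response), with `f` a bivariate
#' locally weighted linear smooth of the subject coordinates.  When `span`
#' is `NULL` the span is chosen by minimising AIC over `grid`, ties broken
#' toward the larger (smoother) span.  The AIC is
#' `deviance + 2 * edf` with `edf` the trace of the smoother operator at
#' the converged weights.
#'
#' @param data A `point_dataset`.
#' @param span LOESS span in (0, 1], or `NULL` to select by AIC.
#' @param grid Candidate spans used when `span` is `NULL`.
#' @param max_iter,tol Local-scoring iteration cap and relative-deviance
#'   convergence tolerance.
#' @return An object of class `gamloess`: fitted log odds `eta`,
#'   `deviance`, `null_deviance`, `dev_diff`, effective degrees of freedom
#'   `edf`, `aic`, `span`, convergence information, and for a selected span
#'   the AIC profile over the grid.
#' @examples
#' d <- generate_dataset(scenario_config(1, 0.2, 3, n_subjects = 300, seed = 1))
#' f <- gamloess(d, span = 0.5)
#' f
#' @export
gamloess <- function(data, span = NULL, grid = span_grid(),
                     max_iter = 50L, tol = 1e-8) {
  check_nondegenerate(data)
  cache <- make_loess_cache(data$coords)
  if (is.null(span)) {
    sel <- select_optimal_span(data, grid, cache = cache,
                               max_iter = max_iter, tol = tol)
    fit <- sel$fit
    fit$aic_profile <- sel$profile
    return(fit)
  }
  fit_gam_at(data, span, cache, max_iter = max_iter, tol = tol)
}

fit_gam_at <- function(data, span, cache, max_iter = 50L, tol = 1e-8,
                       mu_init = NULL) {
  pre <- cache_data_pre(cache, span)
  core <- fit_gam_core(data$outcome, pre, max_iter = max_iter, tol = tol,
                       mu_init = mu_init)
  if (!core$converged)
    warning(sprintf("local scoring did not converge in %d iterations (span %.2f)",
                    core$n_iter, span))
  nd <- null_deviance(data)
  structure(list(span = span, eta = core$eta, fitted = core$mu,
                 deviance = core$deviance, null_deviance = nd,
                 dev_diff = nd - core$deviance, edf = core$edf,
                 aic = core$deviance + 2 * core$edf,
                 converged = core$converged, n_iter = core$n_iter,
                 working = list(z = core$z, w = core$w),
                 data = data),
            class = "gamloess")
}

#' Default span grid
#'
#' Candidate spans 0.05, 0.10, ..., 0.95 used for AIC span selection.
#' @param from,to,by Grid limits and step.
#' @return Numeric vector of spans.
#' @export
span_grid <- function(from = 0.05, to = 0.95, by = 0.05) {
  seq(from, to, by = by)
}

#' Select the LOESS span minimising the GAM AIC
#'
#' Fits the GAM at every span in `grid` and returns the span with minimal
#' AIC; exact ties are broken toward the larger span.
#'
#' @inheritParams gamloess
#' @param cache Internal neighbourhood cache (reused by the permutation
#'   tests); leave `NULL`.
#' @return A list: `span`, the winning `fit`, and the AIC `profile`
#'   (data frame of span, deviance, edf, aic, converged).
#' @export
select_optimal_span <- function(data, grid = span_grid(), cache = NULL,
                                max_iter = 50L, tol = 1e-8) {
  check_nondegenerate(data)
  if (length(grid) < 1) stop("span grid is empty")
  if (is.null(cache)) cache <- make_loess_cache(data$coords)
  n <- nrow(data$coords)
  fits <- vector("list", length(grid))
  warm <- NULL  # successive grid fits warm-start from the previous span
  prev_q <- -1L
  for (i in seq_along(grid)) {
    q_i <- as.integer(ceiling(grid[i] * n))
    if (q_i == prev_q && i > 1 && !inherits(fits[[i - 1]], "error")) {
      # identical neighbourhood size: identical model, reuse the fit so
      # the AIC tie is exact
      fits[[i]] <- fits[[i - 1]]
      fits[[i]]$span <- grid[i]
      next
    }
    fits[[i]] <- tryCatch(
      fit_gam_at(data, grid[i], cache, max_iter = max_iter, tol = tol,
                 mu_init = warm),
      error = function(e) e)
    if (!inherits(fits[[i]], "error")) {
      warm <- fits[[i]]$fitted
      prev_q <- q_i
    }
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("GAM fit failed at every span in the grid")
  aics <- vapply(fits[ok], `[[`, numeric(1), "aic")
  spans_ok <- grid[ok]
  # minimal AIC; ties toward the larger span
  best <- which(aics <= min(aics))
  pick <- best[which.max(spans_ok[best])]
  profile <- data.frame(
    span = spans_ok, deviance = vapply(fits[ok], `[[`, numeric(1), "deviance"),
    edf = vapply(fits[ok], `[[`, numeric(1), "edf"), aic = aics,
    converged = vapply(fits[ok], `[[`, logical(1), "converged"))
  list(span = spans_ok[pick], fit = fits[ok][[pick]], profile = profile)
}

#' @export
print.gamloess <- function(x, ...) {
  cat("Logistic GAM with bivariate LOESS smooth of location\n")
  cat(sprintf("  span %.2f, n = %d, cases = %d\n", x$span,
              length(x$data$outcome), sum(x$data$outcome)))
  cat(sprintf("  deviance %.3f (null %.3f, difference %.3f)\n",
              x$deviance, x$null_deviance, x$dev_diff))
  cat(sprintf("  edf %.2f, AIC %.3f%s\n", x$edf, x$aic,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
summary.gamloess <- function(object, ...) {
  out <- list(span = object$span, deviance = object$deviance,
              null_deviance = object$null_deviance,
              dev_diff = object$dev_diff, edf = object$edf,
              aic = object$aic, converged = object$converged,
              n_iter = object$n_iter,
              eta_range = range(object$eta),
              aic_profile = object$aic_profile)
  class(out) <- "summary.gamloess"
  out
}

#' @export
print.summary.gamloess <- function(x, ...) {
  cat("Logistic GAM (bivariate LOESS), span", format(x$span), "\n")
  cat(sprintf("  deviance %.3f  null %.3f  difference %.3f\n",
              x$deviance, x$null_deviance, x$dev_diff))
  cat(sprintf("  edf %.2f  AIC %.3f  (%s in %d iterations)\n", x$edf, x$aic,
              if (x$converged) "converged" else "no convergence", x$n_iter))
  cat(sprintf("  fitted log odds in [%.3f, %.3f]\n",
              x$eta_range[1], x$eta_range[2]))
  if (!is.null(x$aic_profile)) {
    cat("  AIC profile over the span grid:\n")
    print(x$aic_profile, row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' Predict log odds from a fitted GAM
#'
#' Evaluates the converged LOESS smooth (working response and weights from
#' the final scoring iteration) at new locations.  At a subject location
#' the prediction equals that subject's fitted log odds.  Probe points
#' outside the study region are extrapolations and raise a warning.
#'
#' @param object A `gamloess` fit.
#' @param newdata m x 2 matrix (or data frame with columns x, y) of probe
#'   locations; default: the subject locations.
#' @param type `"link"` for log odds, `"response"` for probabilities.
#' @param ... Unused.
#' @return Numeric vector of length m.
#' @export
predict.gamloess <- function(object, newdata = NULL,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$eta
  } else {
    probes <- as_coord_matrix(newdata)
    if (!all(in_region(object$data$region, probes)))
      warning("probe point(s) outside the study region; extrapolating")
    pre <- loess2d_precompute(object$data$coords, probes,
                              span_to_q(object$span, nrow(object$data$coords)),
                              self_positions(object$data$coords, probes))
    eta <- loess2d_apply(pre, object$working$z, object$working$w, FALSE)$fitted
  }
  if (type == "response") plogis(eta) else eta
}

#' @export
residuals.gamloess <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$data$outcome
  mu <- object$fitted
  if (type == "pearson") return((y - mu) / sqrt(mu * (1 - mu)))
  sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu)))
}

#' @export
simulate.gamloess <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(
    matrix(rbinom(n * nsim, 1L, rep(object$fitted, nsim)), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the fitted log-odds surface
#'
#' Images the predicted log odds on a rectangular grid clipped to the study
#' region, with subject locations overplotted (cases filled).
#'
#' @param x A `gamloess` fit.
#' @param grid_n Grid resolution per axis.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gamloess <- function(x, grid_n = 60, ...) {
  reg <- x$data$region
  cx <- reg$center[1]; cy <- reg$center[2]; r <- reg$radius
  gx <- seq(cx - r, cx + r, length.out = grid_n)
  gy <- seq(cy - r, cy + r, length.out = grid_n)
  gg <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- in_region(reg, gg)
  eta <- rep(NA_real_, nrow(gg))
  eta[inside] <- suppressWarnings(predict(x, gg[inside, , drop = FALSE]))
  image(gx, gy, matrix(eta, grid_n, grid_n), xlab = "x", ylab = "y",
        main = sprintf("Predicted log odds (span %.2f)", x$span), ...)
  pts <- x$data$coords
  points(pts[x$data$outcome == 0, , drop = FALSE], pch = 1, cex = 0.4)
  points(pts[x$data$outcome == 1, , drop = FALSE], pch = 16, cex = 0.4)
  invisible(x)
}
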