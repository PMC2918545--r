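test_that("local linear fits reproduce constants and planes exactly", {
  set.seed(1)
  xy <- cbind(runif(60), runif(60))
  for (sp in c(0.2, 0.5, 0.95)) {
    f <- loess2d(xy, rep(4.2, 60), span = sp)
    expect_equal(f$fitted, rep(4.2, 60), tolerance = 1e-12)
  }
  z <- 1 + 2 * xy[, 1] - 3 * xy[, 2]
  f <- loess2d(xy, z, span = 0.95)
  expect_equal(f$fitted, z, tolerance = 1e-10)
  # and at off-data evaluation points
  ev <- cbind(runif(10), runif(10))
  f <- loess2d(xy, z, span = 0.95, eval_points = ev)
  expect_equal(f$fitted, 1 + 2 * ev[, 1] - 3 * ev[, 2], tolerance = 1e-10)
})

test_that("a prediction equals an explicit weighted least-squares solve", {
  set.seed(2)
  xy <- cbind(runif(20), runif(20))
  z <- sin(5 * xy[, 1]) + xy[, 2]^2
  wprior <- runif(20, 0.5, 2)
  t0 <- c(0.4, 0.6)
  span <- 0.5
  q <- ceiling(span * 20)
  # independent oracle: neighbourhood, tricube and normal equations by hand
  d <- sqrt((xy[, 1] - t0[1])^2 + (xy[, 2] - t0[2])^2)
  dq <- sort(d)[q]
  keep <- d <= dq
  w <- (1 - (d[keep] / dq)^3)^3 * wprior[keep]
  X <- cbind(1, xy[keep, 1] - t0[1], xy[keep, 2] - t0[2])
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * z[keep]))
  f <- loess2d(xy, z, span, weights = wprior,
               eval_points = matrix(t0, 1))
  expect_equal(f$fitted, beta[1], tolerance = 1e-9)
})

test_that("smoother trace matches brute-force operator assembly", {
  set.seed(3)
  n <- 25
  xy <- cbind(runif(n), runif(n))
  wprior <- runif(n, 0.5, 1.5)
  for (sp in c(0.3, 0.7)) {
    # operator columns by linearity: L e_j
    L <- vapply(seq_len(n), function(j) {
      ej <- rep(0, n); ej[j] <- 1
      loess2d(xy, ej, sp, weights = wprior)$fitted
    }, numeric(n))
    f <- loess2d(xy, rnorm(n), sp, weights = wprior, hat = "diag")
    expect_equal(f$trace, sum(diag(L)), tolerance = 1e-9)
    # the dense-rows path agrees with the basis-vector assembly
    r <- loess2d(xy, rnorm(n), sp, weights = wprior, hat = "rows")
    expect_equal(r$rows, L, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("trace is bounded below by a planar fit and decreases with span", {
  set.seed(4)
  xy <- cbind(runif(100), runif(100))
  tr1 <- smoother_trace(xy, 1.0)
  expect_gt(tr1, 3)
  expect_lt(tr1, 8)  # span 1 is close to one global planar fit
  for (s in 1:5) {
    set.seed(s)
    xy <- cbind(runif(80), runif(80))
    tr <- vapply(span_grid(), function(sp) smoother_trace(xy, sp), numeric(1))
    expect_true(all(diff(tr) <= 1e-8))
    # minimal neighbourhoods (q = 4: one tricube-zero boundary point)
    # interpolate, so the trace attains n exactly at the smallest span
    expect_true(all(tr > 3 - 1e-8 & tr <= 80 + 1e-9))
  }
})

test_that("predictions are local: distant responses do not matter", {
  set.seed(5)
  n <- 60
  xy <- cbind(runif(n), runif(n))
  z <- rnorm(n)
  span <- 0.3
  q <- ceiling(span * n)
  t0 <- matrix(c(0.5, 0.5), 1)
  d <- sqrt((xy[, 1] - 0.5)^2 + (xy[, 2] - 0.5)^2)
  outside <- which(d > sort(d)[q])
  z2 <- z
  z2[outside] <- z2[outside] + rnorm(length(outside), sd = 10)
  f1 <- loess2d(xy, z, span, eval_points = t0)$fitted
  f2 <- loess2d(xy, z2, span, eval_points = t0)$fitted
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("mirroring the coordinates mirrors the fitted surface", {
  set.seed(6)
  xy <- cbind(runif(40), runif(40))
  z <- rnorm(40)
  f1 <- loess2d(xy, z, 0.5)$fitted
  f2 <- loess2d(cbind(-xy[, 1], xy[, 2]), z, 0.5)$fitted
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("degenerate neighbourhoods are rejected or regularised", {
  xy <- cbind(runif(10), runif(10))
  expect_error(loess2d(xy, rnorm(10), span = 0.2), "neighbourhood")
  expect_error(loess2d(xy, rnorm(10), 0.5, weights = rep(0, 10)), "weights")
  # collinear neighbourhood: ridge fallback still returns finite values
  xyc <- cbind(seq(0, 1, length.out = 12), 0.5)
  f <- loess2d(xyc, rnorm(12), span = 0.5)
  expect_true(all(is.finite(f$fitted)))
})
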