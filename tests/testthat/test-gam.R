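test_that("null deviance matches the closed form and is symmetric in labels", {
  reg <- region_square(0.5, c(0.5, 0.5))
  mk <- function(y) point_dataset(cbind(runif(length(y)), runif(length(y))),
                                  y, reg)
  set.seed(1)
  d <- mk(rep(c(0L, 1L), each = 500))
  expect_equal(null_deviance(d), 2 * 1000 * log(2), tolerance = 1e-12)
  d1 <- mk(c(1L, rep(0L, 99)))
  d2 <- mk(c(0L, rep(1L, 99)))
  expect_equal(null_deviance(d1), null_deviance(d2))
})

test_that("the fitted GAM is nested in the intercept-only model", {
  d <- generate_dataset(scenario_config(2, 0.2, 2, 400, seed = 3))
  for (sp in c(0.2, 0.6, 0.95)) {
    f <- gamloess(d, span = sp)
    expect_gte(f$dev_diff, -1e-6)
    expect_equal(f$aic, f$deviance + 2 * f$edf)
    expect_true(f$edf > 3 - 1e-6 && f$edf < length(d$outcome))
  }
})

test_that("fitted log odds track a known monotone truth", {
  # truth linear in x: the smooth should agree with the logistic oracle
  set.seed(4)
  reg <- region_square(0.5, c(0.5, 0.5))
  xy <- cbind(runif(1000), runif(1000))
  eta <- -1.5 + 2.5 * (xy[, 1] - 0.5)
  d <- point_dataset(xy, rbinom(1000, 1, plogis(eta)), reg)
  f <- gamloess(d, span = 0.5)
  X <- cbind(1, xy[, 1])
  or_fit <- suppressWarnings(glm.fit(X, d$outcome, family = binomial()))
  eta_glm <- X %*% coef(or_fit)
  expect_gt(cor(f$eta, eta_glm), 0.9)
})

test_that("AIC span selection uses the documented grid and tie rule", {
  expect_equal(range(span_grid()), c(0.05, 0.95))
  expect_equal(diff(span_grid())[1], 0.05)
  # spans mapping to the same neighbourhood size give equal AIC: the tie
  # must resolve to the larger span
  d <- unit_square_dataset(10, p = 0.4, seed = 5)
  sel <- suppressWarnings(select_optimal_span(d, grid = c(0.41, 0.45)))
  expect_equal(sel$span, 0.45)
  expect_equal(sel$profile$aic[1], sel$profile$aic[2])
})

test_that("deviance, edf and AIC are invariant to subject order", {
  d <- generate_dataset(scenario_config(3, 0.2, 2.5, 300, seed = 6))
  set.seed(7)
  p <- sample(length(d$outcome))
  d2 <- point_dataset(d$coords[p, ], d$outcome[p], d$region)
  f1 <- gamloess(d, span = 0.4)
  f2 <- gamloess(d2, span = 0.4)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-9)
  expect_equal(f1$edf, f2$edf, tolerance = 1e-7)
  expect_equal(f2$eta, f1$eta[p], tolerance = 1e-9)
})

test_that("prediction at a subject location returns that subject's log odds", {
  d <- generate_dataset(scenario_config(2, 0.2, 3, 250, seed = 8))
  f <- gamloess(d, span = 0.5)
  idx <- c(3, 50, 200)
  expect_equal(predict(f, d$coords[idx, ]), f$eta[idx], tolerance = 1e-12)
  expect_equal(predict(f, type = "response"), plogis(f$eta))
  expect_warning(predict(f, matrix(c(5, 5), 1)), "outside")
})

test_that("flat-truth probe predictions centre on the marginal log odds", {
  probe <- matrix(c(0, 0), 1)
  preds <- vapply(1:15, function(i) {
    d <- generate_dataset(scenario_config(2, 0.2, 1, 400, seed = 500 + i))
    f <- gamloess(d, span = 0.9)
    c(predict(f, probe), qlogis(mean(d$outcome)))
  }, numeric(2))
  expect_lt(abs(mean(preds[1, ] - preds[2, ])), 3 * sd(preds[1, ]) / sqrt(15))
})

test_that("strong radial effects raise the centre probe above the edge", {
  diffs <- vapply(1:10, function(i) {
    d <- generate_dataset(scenario_config(2, 0.2, 3.5, 600, seed = 600 + i))
    f <- gamloess(d, span = 0.5)
    r <- d$region$radius
    edge <- r * 0.98 * cbind(cos(seq(0, 2 * pi, length.out = 9)),
                             sin(seq(0, 2 * pi, length.out = 9)))
    predict(f, matrix(c(0, 0), 1)) - mean(predict(f, edge))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("simulate and residuals methods behave like a binomial model", {
  d <- generate_dataset(scenario_config(1, 0.2, 2, 200, seed = 9))
  f <- gamloess(d, span = 0.6)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(200L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  rd <- residuals(f)
  expect_equal(sum(rd^2), f$deviance, tolerance = 1e-9)
})
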