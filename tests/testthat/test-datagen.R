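test_that("uniform sampling covers square and disk regions correctly", {
  sq <- region_square(0.5, c(0.5, 0.5))
  pts <- sample_region_points(sq, 1e5, seed = 1)
  se <- sqrt(1 / 12 / 1e5)
  expect_lt(abs(mean(pts[, 1]) - 0.5), 3 * se)
  expect_lt(abs(mean(pts[, 2]) - 0.5), 3 * se)

  dk <- region_disk(2, c(1, -1))
  pts <- sample_region_points(dk, 1e5, seed = 2)
  expect_true(all(in_region(dk, pts)))
  # area ratio: fraction within half the radius is (1/2)^2
  frac <- mean((pts[, 1] - 1)^2 + (pts[, 2] + 1)^2 <= 1)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))

  expect_identical(sample_region_points(dk, 50, seed = 7),
                   sample_region_points(dk, 50, seed = 7))
  expect_error(sample_region_points(dk, 0), "positive")
})

test_that("true log odds follow the three scenario patterns", {
  for (case_id in 1:3) {
    reg <- case_region(case_id)
    cfg <- scenario_config(case_id, 0.2, 1.0)
    pts <- sample_region_points(reg, 200, seed = 3)
    expect_equal(true_logodds(reg, cfg, pts), rep(qlogis(0.2), 200))
  }
  # scenario 2: a subject at the centre has odds OR * p/(1-p)
  reg <- case_region(2)
  cfg <- scenario_config(2, 0.2, 3.0)
  eta <- true_logodds(reg, cfg, matrix(c(0, 0), 1))
  expect_equal(plogis(eta), 3 * 0.25 / (1 + 3 * 0.25))
  # scenario 1 inside the cluster: closed-form odds transform
  reg <- case_region(1)
  cfg <- scenario_config(1, 0.2, 3.0)
  eta_in <- true_logodds(reg, cfg, matrix(c(0.1, 0), 1))
  expect_equal(plogis(eta_in), 0.428571428571, tolerance = 1e-9)
  eta_out <- true_logodds(reg, cfg, matrix(c(0.3, 0), 1))
  expect_equal(plogis(eta_out), 0.2)
})

test_that("generated datasets match their scenario's marginal structure", {
  # scenario 1: cluster holds ~15% of subjects
  n_in <- vapply(1:40, function(i) {
    d <- generate_dataset(scenario_config(1, 0.2, 3, 1000, seed = 100 + i))
    sum(exposure_score(d$region, 1, d$coords))
  }, numeric(1))
  expect_lt(abs(mean(n_in) - 150), 3 * sqrt(150 * 0.85 / 40))

  # flat truth: case rate is the Bernoulli rate
  d <- generate_dataset(scenario_config(1, 0.2, 1, 1e5, seed = 9))
  expect_lt(abs(mean(d$outcome) - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))

  # in-cluster case rate matches the closed-form probability
  rate_in <- vapply(1:30, function(i) {
    d <- generate_dataset(scenario_config(1, 0.2, 3, 1000, seed = 200 + i))
    inc <- exposure_score(d$region, 1, d$coords) == 1
    c(sum(d$outcome[inc]), sum(inc))
  }, numeric(2))
  expect_lt(abs(sum(rate_in[1, ]) / sum(rate_in[2, ]) - 3 * 0.25 / 1.75),
            3 * sqrt(0.43 * 0.57 / sum(rate_in[2, ])))
})

test_that("locations are uniform on a quadrant partition across seeds", {
  reg <- case_region(1)
  pvals <- vapply(1:40, function(i) {
    pts <- sample_region_points(reg, 800, seed = 300 + i)
    quad <- 1 + (pts[, 1] > 0) + 2 * (pts[, 2] > 0)
    suppressWarnings(chisq.test(tabulate(quad, 4))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("scenario 3 has no vertical risk gradient", {
  rej <- vapply(1:100, function(i) {
    d <- generate_dataset(scenario_config(3, 0.2, 3, 600, seed = 400 + i))
    X <- cbind(1, d$coords[, 2])
    fit <- suppressWarnings(glm.fit(X, d$outcome, family = binomial()))
    w <- fit$fitted.values * (1 - fit$fitted.values)
    v <- solve(crossprod(X, X * w))[2, 2]
    abs(coef(fit)[2] / sqrt(v)) > qnorm(0.975)
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("test statistics are invariant to rescaling the region", {
  d <- generate_dataset(scenario_config(1, 0.2, 3, 200, seed = 17))
  reg2 <- region_disk(d$region$radius * 10,
                      cluster_radius = d$region$cluster_radius * 10)
  d2 <- point_dataset(d$coords * 10, d$outcome, reg2)
  expect_equal(most_likely_cluster(d2)$llr, most_likely_cluster(d)$llr)
  expect_equal(sort(most_likely_cluster(d2)$members),
               sort(most_likely_cluster(d)$members))
  f1 <- gamloess(d, span = 0.5)
  f2 <- gamloess(d2, span = 0.5)
  expect_equal(f2$deviance, f1$deviance, tolerance = 1e-8)
  expect_equal(f2$edf, f1$edf, tolerance = 1e-6)
})

test_that("dataset and region constructors validate their input", {
  expect_error(region_disk(1, cluster_radius = 1.2), "smaller")
  expect_error(scenario_config(4, 0.2, 1), "case_id")
  expect_error(scenario_config(1, 0, 1))
  reg <- region_square(0.5, c(0.5, 0.5))
  expect_error(point_dataset(cbind(0.5, 0.5), 2L, reg), "row 1")
  expect_error(point_dataset(cbind(2, 0.5), 1L, reg), "outside")
  d <- point_dataset(cbind(c(0.2, 0.8), c(0.2, 0.8)), c(1L, 1L), reg)
  expect_true(d$degenerate)
  expect_error(null_deviance(d), "degenerate")
})
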