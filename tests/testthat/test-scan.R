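test_that("the zone log-likelihood ratio matches direct evaluation", {
  # balanced zone at the null proportion carries no evidence
  expect_equal(bernoulli_llr(5, 10, 50, 100, "high"), 0)
  expect_equal(bernoulli_llr(5, 10, 50, 100, "low"), 0)
  # all five cases of ten subjects inside a five-subject zone
  expect_equal(bernoulli_llr(5, 5, 5, 10, "high"), 10 * log(2),
               tolerance = 1e-12)
  # case/control relabelling swaps the directions
  expect_equal(bernoulli_llr(4, 6, 10, 30, "high"),
               bernoulli_llr(2, 6, 20, 30, "low"), tolerance = 1e-12)
  # requested direction must match the zone's deviation
  expect_equal(bernoulli_llr(4, 6, 10, 30, "low"), 0)
  expect_error(bernoulli_llr(7, 6, 10, 30, "high"), "inconsistent")
  expect_error(bernoulli_llr(3, 6, 2, 30, "high"), "inconsistent")
})

test_that("the most likely cluster equals exhaustive enumeration on toys", {
  for (s in 1:6) {
    set.seed(s)
    n <- c(8, 12, 15)[1 + s %% 3]
    reg <- region_square(0.5, c(0.5, 0.5))
    y <- rbinom(n, 1, 0.4)
    if (all(y == 0) || all(y == 1)) y[1] <- 1 - y[1]
    d <- point_dataset(cbind(runif(n), runif(n)), as.integer(y), reg)
    m <- most_likely_cluster(d)
    expect_equal(m$llr, scan_oracle(d$coords, d$outcome), tolerance = 1e-9)
    expect_lte(m$n_z, n %/% 2)
    if (m$n_z > 0) {
      # reported counts are consistent with the membership list
      expect_equal(m$c_z, sum(d$outcome[m$members]))
      expect_equal(m$radius,
                   max(sqrt(colSums((t(d$coords[m$members, , drop = FALSE]) -
                                     d$coords[m$members[1], ])^2))),
                   tolerance = 1e-12)
    }
  }
})

test_that("cluster membership is invariant to translation", {
  d <- unit_square_dataset(60, p = 0.35, seed = 7)
  m1 <- most_likely_cluster(d)
  reg2 <- region_square(0.5, c(10.5, -4.5))
  d2 <- point_dataset(sweep(d$coords, 2, c(10, -5), "+"), d$outcome, reg2)
  m2 <- most_likely_cluster(d2)
  expect_equal(m1$members, m2$members)
  expect_equal(m1$llr, m2$llr, tolerance = 1e-9)
})

test_that("adding a case inside the cluster cannot weaken it", {
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    d <- unit_square_dataset(n, p = 0.3, seed = s)
    m <- most_likely_cluster(d, "high")
    ctrl <- m$members[d$outcome[m$members] == 0]
    if (m$n_z == 0 || !length(ctrl)) next
    y2 <- d$outcome
    y2[ctrl[1]] <- 1L
    m2 <- most_likely_cluster(point_dataset(d$coords, y2, d$region), "high")
    expect_gte(m2$llr, m$llr - 1e-9)
  }
})

test_that("Monte Carlo p-values match a direct R re-implementation", {
  for (s in 1:3) {
    set.seed(100 + s)
    d <- unit_square_dataset(50, p = 0.3, seed = 100 + s)
    st <- scan_test(d, n_mc = 150, seed = s)
    # replay the same RNG stream with the oracle scanner
    set.seed(s)
    n <- length(d$outcome)
    obs <- scan_oracle(d$coords, d$outcome)
    nge <- 0
    yy <- d$outcome
    for (r in 1:150) {
      for (i in n:2) {
        j <- floor(runif(1) * i) + 1
        t <- yy[i]; yy[i] <- yy[j]; yy[j] <- t
      }
      if (scan_oracle(d$coords, yy) >= obs - 1e-9) nge <- nge + 1
    }
    expect_equal(st$p_value, (1 + nge) / 151)
    expect_equal(st$mlc$llr, obs, tolerance = 1e-9)
  }
})

test_that("scan p-values respect their Monte Carlo resolution", {
  d <- generate_dataset(scenario_config(1, 0.2, 6, 300, seed = 21))
  st <- scan_test(d, n_mc = 99, seed = 1)
  expect_gte(st$p_value, 1 / 100)
  st2 <- scan_test(d, n_mc = 99, seed = 1)
  expect_identical(st$p_value, st2$p_value)
  expect_identical(st$mlc$members, st2$mlc$members)
})

test_that("direction restriction changes which deviations are found", {
  # a cold cluster: low-rate zone in the middle of an elevated background
  set.seed(22)
  reg <- region_square(0.5, c(0.5, 0.5))
  xy <- cbind(runif(300), runif(300))
  inside <- (xy[, 1] - 0.5)^2 + (xy[, 2] - 0.5)^2 <= 0.15^2
  y <- rbinom(300, 1, ifelse(inside, 0.02, 0.5))
  d <- point_dataset(xy, as.integer(y), reg)
  m_low <- most_likely_cluster(d, "low")
  expect_equal(m_low$direction, "low")
  m_both <- most_likely_cluster(d)
  expect_gte(m_both$llr, m_low$llr - 1e-9)
  m_high <- most_likely_cluster(d, "high")
  expect_true(m_high$direction == "high")
})
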