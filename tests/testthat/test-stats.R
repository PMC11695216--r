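# Exhaustive Mann-Whitney null enumeration: P(W <= w_obs) over all
# C(m + n, m) equally likely rank assignments (no ties).
mw_exact_p_less <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(m + n, m)
  stats <- colSums(matrix(subsets, nrow = m)) - m * (m + 1) / 2
  mean(stats <= w_obs)
}

test_that("repeatability is the median absolute pairwise difference", {
  expect_equal(repeatability_at_point(c(1, 2, 4)), 2)     # pairs 1, 3, 2
  expect_equal(repeatability_at_point(c(3, 5)), 2)
  expect_equal(repeatability_at_point(rep(7, 5)), 0)
  expect_error(repeatability_at_point(3), class = "validation_error")
})

test_that("repeatability is translation invariant and scale equivariant", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), 20, 3)
    shift <- runif(1, -50, 50); c0 <- runif(1, -3, 3)
    expect_equal(repeatability_at_point(x + shift), repeatability_at_point(x))
    expect_equal(repeatability_at_point(c0 * x),
                 abs(c0) * repeatability_at_point(x))
  }
})

test_that("noninferiority p-values match exhaustive enumeration for tiny samples", {
  set.seed(61)
  for (i in 1:5) {
    conf <- round(runif(4, 0, 10), 3)
    std <- round(runif(5, 0, 10), 3)
    res <- mann_whitney_noninferiority(conf, std, margin = 1)
    expect_equal(res$p_value, mw_exact_p_less(conf - 1, std), tolerance = 1e-12)
  }
})

test_that("identity of groups shifted by a full margin is detected", {
  set.seed(62)
  vals <- rnorm(200, 1.2, 0.4)
  res <- mann_whitney_noninferiority(vals, vals, margin = 1.0)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$delta, 0, tolerance = 0.05)
})

test_that("at margin zero identical continuous samples give a centred p-value", {
  set.seed(63)
  ps <- replicate(200, {
    mann_whitney_noninferiority(rnorm(15), rnorm(15), margin = 0)$p_value
  })
  expect_equal(mean(ps), 0.5, tolerance = 0.06)
})

test_that("the Hodges-Lehmann effect and one-sided bound track a known shift", {
  set.seed(64)
  std <- rnorm(60, 10, 1)
  conf <- rnorm(60, 12, 1)
  res <- mann_whitney_noninferiority(conf, std, margin = 1)
  expect_equal(res$delta, 2, tolerance = 0.4)
  expect_gt(res$ci_upper, res$delta)
  expect_error(mann_whitney_noninferiority(numeric(0), std),
               class = "validation_error")
})

test_that("a huge margin is powered at the smallest rejectable design", {
  res <- sample_size_search(margin = 10, reps = 100, seed = 5, n_start = 4)
  # group sizes must merely be large enough for the test to reject at all
  expect_lte(res$n_conf, 8L)
  expect_equal(res$power, 1)
  expect_error(sample_size_search(reps = 50), class = "validation_error")
})

test_that("estimated power is monotone under common random numbers", {
  # fixed seed batch, increasing n via decreasing power target
  r1 <- sample_size_search(power_target = 0.5, reps = 200, seed = 9)
  r2 <- sample_size_search(power_target = 0.9, reps = 200, seed = 9)
  expect_lte(r1$n_conf, r2$n_conf)
  expect_gte(r2$power, 0.9)
})

test_that("doubling the configurable spread does not shrink the required cohort", {
  r1 <- sample_size_search(sd_conf = 1.1, power_target = 0.8, reps = 200, seed = 13)
  r2 <- sample_size_search(sd_conf = 2.2, power_target = 0.8, reps = 200, seed = 13)
  expect_gte(r2$n_conf, r1$n_conf)
})

test_that("an unreachable power target raises a search-limit error", {
  expect_error(sample_size_search(sd_conf = 30, margin = 0.01,
                                  power_target = 0.99, reps = 100, seed = 2,
                                  n_max = 12),
               class = "search_limit_error")
})

test_that("speed regression matches the closed-form least squares", {
  x <- c(0, 0.1, 0.2, 0.4, 0.8)
  y <- c(1.4, 1.3, 1.15, 1.0, 0.6)
  res <- speed_regression(y, x)
  # hand computation: slope = Sxy / Sxx, with t-based 95 % CI
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) + slope * (x - mean(x)))
  se <- sqrt(sum(resid^2) / 3 / sxx)
  expect_equal(res$slope, slope)
  expect_equal(res$ci, slope + c(-1, 1) * qt(0.975, 3) * se, tolerance = 1e-10)
  # a perfectly linear response has R^2 = 1
  res2 <- suppressWarnings(speed_regression(2 - 3 * x, x))
  expect_equal(res2$r_squared, 1)
  expect_equal(res2$slope, -3)
  expect_error(speed_regression(y, rep(1, 5)), class = "degenerate_design_error")
})

test_that("permuting the response de-couples the slope from speed", {
  set.seed(71)
  x <- runif(30, 0, 1)
  y <- 1 + 0.5 * x + rnorm(30, 0, 0.3)
  covered <- replicate(100, {
    ci <- speed_regression(sample(y), x)$ci
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(covered), 0.9)
})

test_that("cohort repeatability tables carry group, speed and point labels", {
  ell <- ellipse_mask(15, 10, scale = 0.5, trajectory_length = 10)
  s1 <- measure_sample(ell$mask, ell$meta, "a", "LONG")
  s2 <- measure_sample(ell$mask, ell$meta, "b", "LONG")
  prof <- quick_profile(list(c(60, 120, 10)), "SHORT", "LONG")
  tab <- cohort_repeatability(list(s1, s2), prof)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$group, rep("configurable", 3))
  expect_equal(tab$speed_mm_s, rep(10 / 120, 3))
  expect_true(all(tab$repeatability_mm == 0))
})
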