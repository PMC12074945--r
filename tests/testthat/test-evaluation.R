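test_that("metric set matches a formula-by-formula oracle", {
  set.seed(20)
  pred <- rnorm(200)
  target <- pred + rnorm(200, 0, 0.5)
  ms <- metric_set(pred, target)
  # naive independent recomputation
  res <- pred - target
  expect_equal(ms$mse, sum(res^2) / 200, tolerance = 1e-12)
  expect_equal(ms$rmse, sqrt(sum(res^2) / 200), tolerance = 1e-12)
  expect_equal(ms$mae, sum(abs(res)) / 200, tolerance = 1e-12)
  expect_equal(ms$r2, 1 - sum(res^2) / sum((target - mean(target))^2),
               tolerance = 1e-12)
  expect_equal(ms$pearson_r,
               sum((pred - mean(pred)) * (target - mean(target))) /
                 sqrt(sum((pred - mean(pred))^2) *
                        sum((target - mean(target))^2)),
               tolerance = 1e-12)
  # internal identities
  expect_equal(ms$rmse^2, ms$mse)
  expect_gte(ms$rmse, ms$mae)  # always, for a common residual set
  expect_lte(abs(ms$pearson_r), 1)
})

test_that("metric set handles perfect fits, constant shifts and edge cases", {
  x <- c(1, 2, 3, 4)
  perfect <- metric_set(x, x)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  shifted <- metric_set(x + 2, x)
  expect_equal(shifted$mae, 2)
  expect_equal(shifted$rmse, 2)
  expect_warning(metric_set(x, rep(1, 4)), "zero variance")
  expect_error(metric_set(1, 1), "at least 2")
  expect_error(metric_set(1:3, 1:4), "lengths differ")
})

test_that("error ratios report signed relative deviations and band fractions", {
  pred <- list(prescription(2, 60, 54, 12), prescription(2, 66, 48, 10))
  target <- list(prescription(2, 60, 60, 12), prescription(2, 60, 48, 12))
  er <- error_ratios(pred, target)
  expect_equal(er$time$ratios, c(-10, 0))      # 54 vs 60 is -10%
  expect_equal(er$intensity$ratios, c(0, 10))
  expect_equal(er$volume$ratios[2], -100 / 6, tolerance = 1e-10)
  expect_equal(er$intensity$within_band, 1)
  # equality: all zero, all within band
  er0 <- error_ratios(target, target)
  for (el in c("intensity", "time", "volume")) {
    expect_equal(er0[[el]]$ratios, c(0, 0))
    expect_equal(er0[[el]]$within_band, 1)
  }
  # counting: exactly 3 of 4 within +/-20 gives 0.75
  p <- cbind(intensity = c(60, 60, 60, 60), time = c(48, 48, 48, 70),
             volume = c(12, 12, 12, 12))
  t_ <- cbind(intensity = c(60, 60, 60, 60), time = c(50, 40, 48, 48),
              volume = c(12, 12, 12, 12))
  expect_equal(error_ratios(p, t_)$time$within_band, 0.75)
  # zero targets are excluded with a warning
  t_[1, "time"] <- 0
  expect_warning(er2 <- error_ratios(p, t_), "zero-target")
  expect_length(er2$time$ratios, 3)
})

test_that("hit rates reproduce whole-percent rates from counts", {
  expect_equal(rate_from_counts(43, 61), 70L)
  expect_equal(rate_from_counts(57, 61), 93L)
  expect_equal(rate_from_counts(21, 32), 66L)
  expect_equal(rate_from_counts(22, 29), 76L)
  expect_equal(rate_from_counts(29, 32), 91L)
  expect_equal(rate_from_counts(28, 29), 97L)
})

test_that("hit-rate bands are inclusive, shift-invariant and use n-1 SD", {
  set.seed(21)
  imp <- rnorm(61, 10, 7)
  hr <- hit_rate(imp, k = 1)
  expect_equal(hr$m, mean(imp))
  expect_equal(hr$sd, sd(imp))
  expect_equal(hr$range, c(hr$m - hr$sd, hr$m + hr$sd))
  expect_equal(hr$rate, rate_from_counts(hr$hits, hr$n))
  # shift invariance: band moves with the mean
  hr2 <- hit_rate(imp + 100, k = 1)
  expect_equal(hr2$hits, hr$hits)
  expect_equal(hr2$rate, hr$rate)
  # wider multiplier never catches fewer points
  expect_gte(hit_rate(imp, k = 1.96)$hits, hr$hits)
  # degenerate data: everything at M hits at any k
  expect_equal(hit_rate(rep(5, 10), k = 1)$rate, 100L)
  expect_error(hit_rate(3), "at least 2")
})

test_that("dropout rate reports one-decimal percent", {
  expect_equal(dropout_rate(64, 61), 4.7)
  expect_equal(dropout_rate(10, 10), 0)
})

test_that("Bland-Altman reports bias, limits and coverage", {
  x <- c(10, 11, 12, 13)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  expect_equal(ba0$coverage, 100)
  # two-point closed form: d = {-1, 1}, sd = sqrt(2)
  ba2 <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_high, 1.96 * sqrt(2))
  expect_equal(ba2$loa_low, -1.96 * sqrt(2))
  # orientation switch flips the sign of the bias
  ba_eo <- bland_altman(c(1, 2, 4), c(2, 2, 2))
  ba_oe <- bland_altman(c(1, 2, 4), c(2, 2, 2),
                        orientation = "observed_minus_expected")
  expect_equal(ba_eo$bias, -ba_oe$bias)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman coverage of Gaussian differences is near 95 percent", {
  set.seed(22)
  n <- 10000
  expected <- rnorm(n, 12, 2)
  observed <- expected + rnorm(n, 0, 0.8)
  ba <- bland_altman(expected, observed)
  expect_lt(abs(ba$coverage - 95), 1)
})

test_that("expected-vs-observed regression matches the closed-form OLS oracle", {
  # exact relations
  e <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(expected_vs_observed_regression(e, 2 * e + 3))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 3)
  expect_equal(r$r2, 1)
  ident <- suppressWarnings(expected_vs_observed_regression(e, e))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  # noisy data against normal equations computed independently
  set.seed(23)
  x <- rnorm(100, 10, 2)
  y <- 1.2 * x - 0.5 + rnorm(100, 0, 0.7)
  fit <- expected_vs_observed_regression(x, y)
  Xa <- cbind(1, x)
  beta <- solve(crossprod(Xa), crossprod(Xa, y))
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-10)
  expect_true(fit$slope_ci[1] < fit$slope && fit$slope < fit$slope_ci[2])
  expect_error(expected_vs_observed_regression(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})
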