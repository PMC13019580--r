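test_that("rmse / mase / pearson match hand-computed examples", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(1, -1), c(-1, 1)), 2)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(mase(c(1, 2, 3, 4), c(1, 3, 3, 5), m = 1), 0.5)
  expect_equal(mase(1:10, 1:10, m = 7), 0)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson(1:5, 2 * (1:5)), 1)
  expect_equal(pearson(1:5, -(1:5) + 10), -1)
})

test_that("metrics match brute-force recomputation on 100 seeded vectors", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(20:60, 1)
    y <- rnorm(n); yhat <- y + rnorm(n, sd = 0.5)
    expect_equal(rmse(y, yhat), sqrt(sum((y - yhat)^2) / n), tolerance = 1e-9)
    m <- sample(1:7, 1)
    expect_equal(mase(y, yhat, m),
                 (sum(abs(y - yhat)) / n) /
                   (sum(abs(diff(y, lag = m))) / (n - m)), tolerance = 1e-9)
    expect_equal(pearson(y, yhat), stats::cor(y, yhat), tolerance = 1e-9)
  }
})

test_that("metric edge cases raise explicit errors", {
  expect_error(rmse(1:3, 1:4), "length mismatch")
  expect_error(mase(rep(2, 10), rnorm(10), m = 7), "degenerate denominator")
  expect_error(mase(1:3, 1:3, m = 3), "length > m")
  expect_error(pearson(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("seasonal-naive forecast scores MASE 1 by construction", {
  set.seed(40)
  m <- 7L
  z <- rnorm(5007)
  # evaluate the m-lag naive on the tail of the series: its absolute errors
  # are the same |z_t - z_{t-m}| terms the MASE denominator averages, so the
  # statistic is anchored at 1 up to the boundary terms of the two ranges
  y <- z[(m + 1):5007]; naive <- z[1:5000]
  expect_equal(mase(y, naive, m), 1, tolerance = 0.05)
})

test_that("metric report macro-averages per-feature values and serializes", {
  set.seed(41)
  y <- matrix(rnorm(200), 50, 4); yhat <- y + rnorm(200, sd = 0.3)
  rep_ <- metric_report(y, yhat, m = 7, feature_names = letters[1:4])
  expect_equal(nrow(rep_$per_feature), 4L)
  expect_equal(rep_$macro$rmse, mean(rep_$per_feature$rmse))
  # permutation invariance of the macro average
  perm <- sample(4)
  rep2 <- metric_report(y[, perm], yhat[, perm], m = 7)
  expect_equal(rep2$macro$rmse, rep_$macro$rmse)
  expect_equal(rep2$macro$pearson, rep_$macro$pearson)
  stem <- tempfile()
  write_metric_report(rep_, stem)
  js <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(js$macro$mase, rep_$macro$mase, tolerance = 1e-12)
  csv <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), 5L)  # 4 features + macro row
  expect_error(metric_report(y, yhat), "must be given")
})

test_that("DM statistic matches an independent textbook formula", {
  for (s in 1:5) {
    set.seed(s)
    n <- 100
    e1 <- rnorm(n); e2 <- rnorm(n, sd = 1.2)
    r <- dm_test(e1, e2, h = 1)
    d <- e1^2 - e2^2
    stat <- mean(d) / sqrt(sum((d - mean(d))^2) / n^2)
    expect_equal(r$statistic, stat, tolerance = 1e-9)
    expect_equal(r$p_value, 2 * pnorm(-abs(stat)), tolerance = 1e-9)
    # antisymmetry
    expect_equal(dm_test(e2, e1)$statistic, -r$statistic, tolerance = 1e-12)
  }
  # h > 1 adds uniform-kernel autocovariance terms
  set.seed(99)
  e1 <- rnorm(50); e2 <- rnorm(50)
  d <- e1^2 - e2^2; dc <- d - mean(d); n <- 50
  v <- sum(dc^2) / n + 2 * sum(dc[2:n] * dc[1:(n - 1)]) / n +
    2 * sum(dc[3:n] * dc[1:(n - 2)]) / n
  expect_equal(dm_test(e1, e2, h = 3)$statistic, mean(d) / sqrt(v / n),
               tolerance = 1e-9)
  expect_error(dm_test(e1, e1), "identically zero")
})

test_that("lag and peak error are recovered by construction", {
  set.seed(42)
  y <- 50 + 10 * sin(2 * pi * (1:200) / 30) + rnorm(200, sd = 0.5)
  r0 <- lag_peak_error(y, y, max_lag = 10)
  expect_equal(r0$lag, 0L)
  expect_equal(r0$peak_error, 0)
  # predictions delayed by 3 days
  yhat <- c(y[1:3], y[1:197])
  expect_equal(lag_peak_error(y, yhat, max_lag = 10)$lag, 3L)
  # 20% amplitude inflation: zero lag, 0.2 peak error
  r2 <- lag_peak_error(y, 1.2 * y, max_lag = 10)
  expect_equal(r2$lag, 0L)
  expect_equal(r2$peak_error, 0.2, tolerance = 1e-12)
  expect_error(lag_peak_error(rep(0, 50), rnorm(50), 10), "max\\(y\\)")
})

test_that("block bootstrap resamples 7-day blocks and is seed-stable", {
  set.seed(43)
  y <- matrix(rnorm(28), 28, 1); yhat <- y + rnorm(28, sd = 0.2)
  ci1 <- block_bootstrap_ci(rmse, y, yhat, block_length = 7, B = 50, seed = 7)
  ci2 <- block_bootstrap_ci(rmse, y, yhat, block_length = 7, B = 50, seed = 7)
  expect_identical(ci1$replicates, ci2$replicates)
  expect_identical(c(ci1$lower, ci1$upper), c(ci2$lower, ci2$upper))
  # degenerate input: metric constant across replications -> zero width
  yc <- matrix(1:28, 28, 1)
  ci0 <- block_bootstrap_ci(function(a, b) 0.5, yc, yc, B = 20, seed = 1)
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$lower, 0.5)
  expect_error(block_bootstrap_ci(rmse, y[1:5, , drop = FALSE],
                                  yhat[1:5, , drop = FALSE], block_length = 7),
               "shorter than one block")
})

test_that("two-level bootstrap perturbs the across-feature stage", {
  set.seed(44)
  y <- matrix(rnorm(28 * 4), 28, 4); yhat <- y + rnorm(28 * 4, sd = 0.2)
  one <- block_bootstrap_ci(rmse, y, yhat, B = 100, seed = 5, two_level = FALSE)
  two <- block_bootstrap_ci(rmse, y, yhat, B = 100, seed = 5, two_level = TRUE)
  expect_equal(one$point, two$point)
  # second-stage resampling adds across-target variance
  expect_gt(stats::var(two$replicates), stats::var(one$replicates) * 0.9)
  expect_true(two$two_level)
})
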