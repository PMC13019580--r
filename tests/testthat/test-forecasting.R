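test_that("oracle model gives zero error in both modes (mode equivalence)", {
  spec <- tiny_window(horizon = 5, ratio = 2)
  p <- random_panel(T_ = 40, F_ = 2, seed = 31)
  om <- oracle_model(p, spec)
  truth <- p$values[26:40, ]
  roll <- rolling_forecast(om, p, test_start = 26, n_ahead = 15)
  expect_equal(unname(roll$predicted), unname(truth), tolerance = 1e-12)
  rec <- recursive_forecast(om, p, test_start = 26, n_ahead = 15)
  expect_equal(unname(rec$predicted), unname(truth), tolerance = 1e-12)
  expect_equal(roll$predicted, rec$predicted, tolerance = 1e-12)
})

test_that("block structure: ceil(span/H) blocks, truncation flagged", {
  spec <- tiny_window(horizon = 5, ratio = 2)
  p <- random_panel(T_ = 41, F_ = 2, seed = 32)
  om <- oracle_model(p, spec)
  fc <- rolling_forecast(om, p, test_start = 27, n_ahead = 15)
  expect_false(fc$truncated)
  expect_equal(nrow(fc$predicted), 15L)
  fc2 <- rolling_forecast(om, p, test_start = 27, n_ahead = 13)
  expect_true(fc2$truncated)
  expect_equal(nrow(fc2$predicted), 13L)
  expect_equal(fc$dates, p$dates[27:41])
})

test_that("causality: rolling inputs never read at or beyond the block origin", {
  # a model that records which values its windows contained
  spec <- tiny_window(horizon = 3, ratio = 2)
  p <- random_panel(T_ = 30, F_ = 1, seed = 33)
  seen <- new.env(); seen$rows <- list()
  spy <- structure(list(cfg = list(window = spec, n_features = 1)),
                   class = c("spy_model", "pedvol_model"))
  registerS3method("model_predict", "spy_model", function(model, inputs, chunk = 64L) {
    seen$rows <- c(seen$rows, list(inputs))
    N <- dim(inputs)[1]
    list(forecast = array(0, c(N, 3, 1)), trend = array(0, c(N, 3, 1)),
         seasonal = array(0, c(N, 3, 1)), residual = array(0, c(N, 3, 1)),
         attention = array(1, c(N, 3, 1, 1)))
  }, envir = asNamespace("pedvol"))
  rolling_forecast(spy, p, test_start = 20, n_ahead = 9)
  # block k predicts rows 20+3(k-1)..; its input must be the 6 rows before
  for (k in 1:3) {
    origin <- 20 + (k - 1) * 3
    expect_equal(as.vector(seen$rows[[k]][1, , 1]),
                 p$values[(origin - 6):(origin - 1), 1], ignore_attr = TRUE)
  }
})

test_that("recursive mode feeds predictions back and never reads test truth", {
  spec <- tiny_window(horizon = 3, ratio = 2)
  p <- random_panel(T_ = 30, F_ = 1, seed = 34)
  # constant-bias model: predicts last observed input value + b each step
  bias_model <- structure(list(cfg = list(window = spec, n_features = 1), b = 1),
                          class = c("bias_model", "pedvol_model"))
  registerS3method("model_predict", "bias_model", function(model, inputs, chunk = 64L) {
    N <- dim(inputs)[1]; H <- 3
    out <- array(0, c(N, H, 1))
    for (k in seq_len(N)) out[k, , 1] <- inputs[k, dim(inputs)[2], 1] + model$b
    list(forecast = out, trend = out * 0, seasonal = out * 0, residual = out * 0,
         attention = array(1, c(N, 3, 1, 1)))
  }, envir = asNamespace("pedvol"))
  rec <- recursive_forecast(bias_model, p, test_start = 20, n_ahead = 9)
  last_obs <- p$values[19, 1]
  # closed-form propagation: block k predicts last_obs + k (bias accumulates
  # because each block's input ends with the previous block's prediction)
  expect_equal(unname(rec$predicted[, 1]), rep(last_obs + 1:3, each = 3))
  # rolling with the same model does not accumulate
  roll <- rolling_forecast(bias_model, p, test_start = 20, n_ahead = 9)
  expect_equal(unname(roll$predicted[, 1]),
               rep(p$values[c(19, 22, 25), 1] + 1, each = 3), ignore_attr = TRUE)
})

test_that("constant model on constant series is exact at any horizon", {
  spec <- tiny_window(horizon = 3, ratio = 2)
  p <- panel_series(as.Date("2020-01-01") + 0:29, matrix(5, 30, 1), "c")
  cm <- structure(list(cfg = list(window = spec, n_features = 1), b = 0),
                  class = c("bias_model", "pedvol_model"))
  rec <- recursive_forecast(cm, p, test_start = 20, n_ahead = 11)
  expect_true(all(rec$predicted == 5))
})

test_that("history shorter than one backcast errors", {
  spec <- tiny_window(horizon = 3, ratio = 2)
  p <- random_panel(T_ = 10, F_ = 1, seed = 35)
  om <- oracle_model(p, spec)
  expect_error(rolling_forecast(om, p, test_start = 5), "insufficient history")
  expect_error(recursive_forecast(om, p, test_start = 5, n_ahead = 3),
               "insufficient history")
  expect_error(recursive_forecast(om, p, test_start = 8, n_ahead = 2),
               "at least one horizon")
})

test_that("forecast CSV export emits the panel dialect", {
  spec <- tiny_window(horizon = 5, ratio = 2)
  p <- random_panel(T_ = 40, F_ = 2, seed = 36)
  om <- oracle_model(p, spec)
  fc <- rolling_forecast(om, p, test_start = 26, n_ahead = 10)
  path <- tempfile(fileext = ".csv")
  write_forecast_csv(fc, path, streams = TRUE)
  back <- read_panel_csv(path)
  expect_equal(back$values, fc$predicted, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(file.exists(sub("\\.csv$", "_trend.csv", path)))
})
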