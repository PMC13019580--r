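#' Multi-step forecasts over a held-out span
#'
#' Both modes advance through the test span in consecutive H-step blocks.
#'
#' *Rolling* prediction re-anchors on truth: every input window contains
#' only observed values, so each block is a genuine H-step-ahead forecast
#' from real history. *Recursive* prediction feeds its own output back:
#' the first block uses observed history, later blocks splice previously
#' predicted values in place of unobserved truth and never read
#' test-period observations, so errors can accumulate with the block
#' index.
#'
#' The panel is expected on the model's (normalized) training scale; use
#' [inverse_transform_panel()] on the result to return to counts. A test
#' span not divisible by H has its final block truncated (flagged in the
#' result).
#'
#' @param model a trained `pedvol_model`.
#' @param panel a `panel_series` on the model scale containing history plus
#'   the span to forecast.
#' @param test_start 1-based row index of the first day to forecast; at
#'   least `L + 1` rows of history must precede it.
#' @param n_ahead number of days to forecast (default: to the end of the
#'   panel). For `recursive_forecast` the panel only needs to reach
#'   `test_start - 1`; `n_ahead` is then required.
#' @return a `forecast_result`: `dates`, `predicted` (T' x F), per-module
#'   streams `trend`/`seasonal`/`residual` (T' x F), `attention`
#'   (3 x F x F mean weights), `mode`, `truncated`.
#' @export
rolling_forecast <- function(model, panel, test_start, n_ahead = NULL) {
  L <- model$cfg$window$backcast; H <- model$cfg$window$horizon
  T_ <- nrow(panel$values)
  if (test_start <= L) stop("insufficient history: need ", L,
                            " observed days before test_start")
  if (is.null(n_ahead)) n_ahead <- T_ - test_start + 1L
  if (n_ahead < 1L || test_start + n_ahead - 1L > T_) {
    stop("rolling mode needs observed values covering the whole span")
  }
  .block_forecast(model, panel$values, panel$dates, test_start, n_ahead,
                  feed_back = FALSE, mode = "rolling",
                  feature_names = panel$feature_names)
}

#' @rdname rolling_forecast
#' @export
recursive_forecast <- function(model, panel, test_start, n_ahead) {
  L <- model$cfg$window$backcast
  if (test_start <= L) stop("insufficient history: need ", L,
                            " observed days before test_start")
  if (n_ahead < model$cfg$window$horizon) {
    stop("n_ahead must be at least one horizon")
  }
  T_ <- nrow(panel$values)
  F_ <- ncol(panel$values)
  # working matrix: observed history then placeholders to be overwritten by
  # predictions; test observations (if present in `panel`) are never read
  work <- matrix(NA_real_, test_start - 1L + n_ahead, F_)
  work[seq_len(test_start - 1L), ] <- panel$values[seq_len(test_start - 1L), ]
  dates <- panel$dates[1L] + seq_len(nrow(work)) - 1L
  .block_forecast(model, work, dates, test_start, n_ahead,
                  feed_back = TRUE, mode = "recursive",
                  feature_names = panel$feature_names)
}

.block_forecast <- function(model, values, dates, test_start, n_ahead,
                            feed_back, mode, feature_names) {
  L <- model$cfg$window$backcast; H <- model$cfg$window$horizon
  F_ <- ncol(values)
  n_blocks <- ceiling(n_ahead / H)
  pred <- matrix(NA_real_, n_ahead, F_)
  s_tr <- matrix(NA_real_, n_ahead, F_)
  s_se <- matrix(NA_real_, n_ahead, F_)
  s_re <- matrix(NA_real_, n_ahead, F_)
  att_sum <- array(0, c(3L, F_, F_))
  for (k in seq_len(n_blocks)) {
    origin <- test_start + (k - 1L) * H  # first day predicted by this block
    hist <- values[(origin - L):(origin - 1L), , drop = FALSE]
    if (anyNA(hist)) stop("internal: window reads unavailable values")
    x <- array(0, c(1L, L, F_)); x[1L, , ] <- hist
    pr <- model_predict(model, x)
    take <- min(H, n_ahead - (k - 1L) * H)
    rows <- (k - 1L) * H + seq_len(take)
    pred[rows, ] <- pr$forecast[1L, seq_len(take), ]
    s_tr[rows, ] <- pr$trend[1L, seq_len(take), ]
    s_se[rows, ] <- pr$seasonal[1L, seq_len(take), ]
    s_re[rows, ] <- pr$residual[1L, seq_len(take), ]
    att_sum <- att_sum + pr$attention[1L, , , ]
    if (feed_back) {
      values[origin:(origin + take - 1L), ] <- pred[rows, , drop = FALSE]
    }
  }
  colnames(pred) <- feature_names
  structure(list(
    dates = dates[test_start:(test_start + n_ahead - 1L)],
    predicted = pred,
    trend = s_tr, seasonal = s_se, residual = s_re,
    attention = att_sum / n_blocks,
    mode = mode,
    truncated = (n_ahead %% H) != 0L,
    feature_names = feature_names),
    class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat("<forecast_result> ", x$mode, " mode, ", nrow(x$predicted), " days x ",
      ncol(x$predicted), " features",
      if (x$truncated) " (final block truncated)", "\n", sep = "")
  invisible(x)
}

#' Write a forecast (and optional module streams) as CSV
#'
#' Emits the same dialect as the input panels: a `date` column plus one
#' column per feature.
#'
#' @param fc a `forecast_result`.
#' @param path output CSV path for the point forecast.
#' @param streams if `TRUE`, also writes `<path stem>_trend.csv`,
#'   `_seasonal.csv`, `_residual.csv`.
#' @return `path`, invisibly.
#' @export
write_forecast_csv <- function(fc, path, streams = FALSE) {
  emit <- function(m, p) {
    df <- data.frame(date = format(fc$dates, "%Y-%m-%d"), m, check.names = FALSE)
    names(df) <- c("date", fc$feature_names)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  }
  emit(fc$predicted, path)
  if (streams) {
    stem <- sub("\\.csv$", "", path)
    emit(fc$trend, paste0(stem, "_trend.csv"))
    emit(fc$seasonal, paste0(stem, "_seasonal.csv"))
    emit(fc$residual, paste0(stem, "_residual.csv"))
  }
  invisible(path)
}
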