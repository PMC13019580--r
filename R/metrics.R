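#' Root-mean-square error
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 1L) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute scaled error
#'
#' Mean absolute prediction error over the series divided by the in-sample
#' mean absolute error of the seasonal-naive forecast with period `m`
#' (i.e. `mean |y_t - y_{t-m}|` over `t = m+1 .. T`). Values below 1 mean
#' the forecast beats the seasonal-naive benchmark on this series.
#'
#' @param y observed series (length T > m).
#' @param yhat predicted series, same length.
#' @param m seasonal period of the naive benchmark; defaults to 7 (the
#'   weekly cycle of daily visit counts).
#' @return the MASE statistic.
#' @export
mase <- function(y, yhat, m = 7L) {
  if (length(y) != length(yhat)) stop("length mismatch")
  T_ <- length(y)
  if (m < 1L || T_ <= m) stop("need series length > m >= 1")
  denom <- mean(abs(y[(m + 1L):T_] - y[seq_len(T_ - m)]))
  if (denom == 0) {
    stop("degenerate denominator: series is constant at seasonal period m = ", m)
  }
  mean(abs(y - yhat)) / denom
}

#' Pearson correlation coefficient
#' @param x first series (length >= 2, non-zero variance).
#' @param y second series.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop("undefined correlation: zero variance")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Per-feature and macro-averaged metric report
#'
#' Computes RMSE, MASE and Pearson correlation per feature plus their
#' macro averages (unweighted arithmetic means over features with finite
#' values). Metrics are intended to be computed on the normalized scale.
#'
#' @param y observed matrix (days x features).
#' @param yhat predicted matrix, same shape.
#' @param m MASE seasonal period (required so reports are self-describing).
#' @param feature_names optional labels.
#' @return a `metric_report`: data.frame `per_feature` (feature, rmse,
#'   mase, pearson) and list `macro`.
#' @export
metric_report <- function(y, yhat, m, feature_names = colnames(y)) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  if (missing(m)) stop("MASE seasonal period m must be given explicitly")
  F_ <- ncol(y)
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(F_))
  one <- function(fn, j) tryCatch(fn(y[, j], yhat[, j]), error = function(e) NA_real_)
  per <- data.frame(
    feature = feature_names,
    rmse = vapply(seq_len(F_), function(j) one(rmse, j), 0),
    mase = vapply(seq_len(F_), function(j) {
      tryCatch(mase(y[, j], yhat[, j], m), error = function(e) NA_real_)
    }, 0),
    pearson = vapply(seq_len(F_), function(j) one(pearson, j), 0))
  macro <- lapply(per[-1L], function(v) mean(v[is.finite(v)]))
  structure(list(per_feature = per, macro = macro, m = m),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> macro: rmse ", signif(x$macro$rmse, 4),
      "  mase ", signif(x$macro$mase, 4),
      "  pearson ", signif(x$macro$pearson, 4),
      "  (m = ", x$m, ", F = ", nrow(x$per_feature), ")\n", sep = "")
  invisible(x)
}

#' Serialize a metric report
#'
#' `write_metric_report` emits both a JSON document and a flat CSV
#' (feature, rmse, mase, pearson; final row `macro`).
#'
#' @param report a `metric_report`.
#' @param stem output path stem; writes `<stem>.json` and `<stem>.csv`.
#' @return the two paths, invisibly.
#' @export
write_metric_report <- function(report, stem) {
  jp <- paste0(stem, ".json"); cp <- paste0(stem, ".csv")
  jsonlite::write_json(list(per_feature = report$per_feature,
                            macro = report$macro, m = report$m),
                       jp, auto_unbox = TRUE, digits = NA, na = "null")
  df <- rbind(report$per_feature,
              data.frame(feature = "macro", rmse = report$macro$rmse,
                         mase = report$macro$mase, pearson = report$macro$pearson))
  utils::write.csv(df, cp, row.names = FALSE)
  invisible(c(jp, cp))
}

#' Diebold-Mariano test of equal forecast accuracy
#'
#' Tests the null of equal expected loss between two forecast error
#' series. The statistic is `mean(d) / sqrt(hac_var(d) / n)` where
#' `d_t = loss(e1_t) - loss(e2_t)` and the HAC variance uses a uniform
#' (truncated) kernel with `h - 1` autocovariance lags, `h` being the
#' forecast horizon. The p-value is two-sided normal; the Harvey
#' small-sample correction (t distribution with n-1 df and the standard
#' scaling factor) is optional and off by default.
#'
#' @param e1,e2 forecast error series of equal length `n > h`.
#' @param h forecast horizon used for the variance lags (default 1).
#' @param loss `"squared"` or `"absolute"`.
#' @param harvey apply the Harvey-Leybourne-Newbold correction.
#' @return a `dm_result`: `statistic`, `p_value`, `d` (loss differential),
#'   `h`, `n`.
#' @export
dm_test <- function(e1, e2, h = 1L, loss = c("squared", "absolute"),
                    harvey = FALSE) {
  loss <- match.arg(loss)
  if (length(e1) != length(e2)) stop("length mismatch")
  n <- length(e1)
  if (n <= h) stop("need n > h")
  g <- if (loss == "squared") function(e) e^2 else abs
  d <- g(e1) - g(e2)
  if (all(d == 0)) stop("identical losses: loss differential is identically zero")
  dbar <- mean(d)
  dc <- d - dbar
  # uniform-kernel HAC long-run variance with h-1 lags
  v <- sum(dc^2) / n
  if (h > 1L) {
    for (k in seq_len(h - 1L)) {
      v <- v + 2 * sum(dc[(k + 1L):n] * dc[seq_len(n - k)]) / n
    }
  }
  if (v <= 0) stop("non-positive HAC variance (loss differential degenerate)")
  stat <- dbar / sqrt(v / n)
  if (harvey) {
    corr <- sqrt((n + 1 - 2 * h + h * (h - 1) / n) / n)
    stat <- stat * corr
    p <- 2 * stats::pt(-abs(stat), df = n - 1)
  } else {
    p <- 2 * stats::pnorm(-abs(stat))
  }
  structure(list(statistic = stat, p_value = p, d = d, h = h, n = n,
                 loss = loss, harvey = harvey),
            class = "dm_result")
}

#' Lag and peak-error quantification of a total-volume forecast
#'
#' `lag` is the shift (in days) maximizing the cross-correlation between
#' the observed and shifted predicted series (mean-centered; ties broken
#' toward the smaller absolute lag; positive lag means predictions trail
#' the truth). `peak_error` is the relative error of the predicted series
#' maximum: `|max(yhat) - max(y)| / max(y)`.
#'
#' @param y observed total series.
#' @param yhat predicted total series, same length.
#' @param max_lag maximum |shift| examined, `< length(y) / 2`.
#' @return list with `lag` (days) and `peak_error` (fraction).
#' @export
lag_peak_error <- function(y, yhat, max_lag = 14L) {
  if (length(y) != length(yhat)) stop("length mismatch")
  n <- length(y)
  if (max_lag >= n / 2) stop("max_lag must be < length/2")
  if (max(y) == 0) stop("peak error undefined: max(y) == 0")
  yc <- y - mean(y); pc <- yhat - mean(yhat)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- yc[seq_len(n - k)]; b <- pc[(1L + k):n]
    } else {
      a <- yc[(1L - k):n]; b <- pc[seq_len(n + k)]
    }
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, 0)
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  lag <- cand[which.min(abs(cand))]
  list(lag = lag, peak_error = abs(max(yhat) - max(y)) / max(y))
}

#' Moving-block bootstrap confidence interval for a forecast metric
#'
#' Resamples contiguous 7-day (by default) blocks of aligned (y, yhat)
#' pairs within each series to preserve short-range serial dependence,
#' recomputes the metric per replication, and reports a percentile
#' interval. With `two_level = TRUE` a second resampling stage draws the
#' F target series with replacement before macro-averaging (stratified
#' two-level scheme for macro metrics).
#'
#' @param metric_fn function `(y, yhat) -> scalar`, e.g. [rmse()].
#' @param y observed matrix (days x features) or vector.
#' @param yhat predictions, same shape.
#' @param block_length block size in days (default 7).
#' @param B bootstrap replications (default 500).
#' @param two_level resample series at a second level before averaging.
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; same seed gives identical endpoints.
#' @return a `bootstrap_ci`: `point`, `lower`, `upper`, `level`,
#'   `block_length`, `B`, `two_level`, `replicates`.
#' @export
block_bootstrap_ci <- function(metric_fn, y, yhat, block_length = 7L,
                               B = 500L, two_level = FALSE, level = 0.95,
                               seed = 1L) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  T_ <- nrow(y); F_ <- ncol(y)
  if (T_ < block_length) stop("series shorter than one block")
  if (B < 2L) stop("need B >= 2")
  set.seed(seed)
  n_blocks <- ceiling(T_ / block_length)
  n_starts <- T_ - block_length + 1L
  macro <- function(ym, pm) {
    mean(vapply(seq_len(ncol(ym)), function(j) metric_fn(ym[, j], pm[, j]), 0))
  }
  point <- macro(y, yhat)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    ys <- matrix(0, T_, F_); ps <- matrix(0, T_, F_)
    for (j in seq_len(F_)) {
      starts <- sample.int(n_starts, n_blocks, replace = TRUE)
      idx <- as.vector(vapply(starts, function(s) s + seq_len(block_length) - 1L,
                              integer(block_length)))[seq_len(T_)]
      ys[, j] <- y[idx, j]; ps[, j] <- yhat[idx, j]
    }
    per <- vapply(seq_len(F_), function(j) metric_fn(ys[, j], ps[, j]), 0)
    if (two_level && F_ > 1L) {
      per <- per[sample.int(F_, F_, replace = TRUE)]
    }
    reps[b] <- mean(per)
  }
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(point = point, lower = qs[1L], upper = qs[2L], level = level,
                 block_length = as.integer(block_length), B = as.integer(B),
                 two_level = two_level, replicates = reps),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat("<bootstrap_ci> ", signif(x$point, 4), " [", signif(x$lower, 4), ", ",
      signif(x$upper, 4), "]  (", x$level * 100, "%, blocks of ",
      x$block_length, ", B = ", x$B,
      if (x$two_level) ", two-level", ")\n", sep = "")
  invisible(x)
}
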