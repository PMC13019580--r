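#' Split-conformal calibration
#'
#' Computes the finite-sample conformal quantile of absolute calibration
#' residuals: the `ceil((n + 1) * (1 - alpha))`-th order statistic of
#' `|residuals|`. With exchangeable calibration and test residuals,
#' symmetric intervals of this half-width cover at least `1 - alpha` of
#' test points marginally.
#'
#' @param residuals calibration residuals (point forecast minus truth),
#'   one series.
#' @param alpha miscoverage level (default 0.05 for 95% intervals).
#' @return a `conformal_calibration`: `q` (base half-width), `alpha`,
#'   `n_cal`.
#' @export
conformal_calibrate <- function(residuals, alpha = 0.05) {
  r <- abs(residuals[is.finite(residuals)])
  n <- length(r)
  rank <- ceiling((n + 1) * (1 - alpha))
  if (n < 1L || rank > n) {
    stop("infeasible level: need at least ", ceiling(1 / alpha) - 1,
         " calibration residuals for alpha = ", alpha, " (have ", n, ")")
  }
  structure(list(q = sort(r)[rank], alpha = alpha, n_cal = n),
            class = "conformal_calibration")
}

#' Seasonal-regime width multipliers
#'
#' The published adaptive band widens intervals by 1.5x during peak
#' periods, keeps 1.0x in normal periods, and shrinks to 0.8x off-peak.
#' Note the off-peak shrinkage voids the distribution-free coverage
#' guarantee in that regime; report per-regime coverage to check it.
#'
#' @param peak,normal,off_peak positive width multipliers.
#' @return a named numeric vector of class `regime_multipliers`.
#' @export
regime_multipliers <- function(peak = 1.5, normal = 1.0, off_peak = 0.8) {
  m <- c(peak = peak, normal = normal, off_peak = off_peak)
  if (any(m <= 0)) stop("multipliers must be positive")
  structure(m, class = "regime_multipliers")
}

#' Label dates by seasonal regime
#'
#' Dates whose seasonal index exceeds the `peak_quantile` of the index are
#' `peak`, those below the `off_quantile` are `off_peak`, the rest
#' (including exact ties and a flat index) are `normal`.
#'
#' @param seasonal_index numeric seasonal component per date (e.g. the
#'   seasonal block's forecast stream, or generator truth in tests).
#' @param peak_quantile upper threshold quantile (default 0.75).
#' @param off_quantile lower threshold quantile (default 0.25).
#' @return factor with levels `off_peak`, `normal`, `peak`.
#' @export
label_regimes <- function(seasonal_index, peak_quantile = 0.75,
                          off_quantile = 0.25) {
  if (!all(is.finite(seasonal_index))) stop("seasonal index must be finite")
  hi <- stats::quantile(seasonal_index, peak_quantile, names = FALSE, type = 7)
  lo <- stats::quantile(seasonal_index, off_quantile, names = FALSE, type = 7)
  lab <- rep("normal", length(seasonal_index))
  lab[seasonal_index > hi] <- "peak"
  lab[seasonal_index < lo] <- "off_peak"
  factor(lab, levels = c("off_peak", "normal", "peak"))
}

#' Build regime-adaptive prediction intervals
#'
#' Interval for each date is `point +/- q * multiplier(regime)`, so the
#' width ratio of peak to normal regimes is exactly `peak / normal`.
#'
#' @param point point forecasts (vector, one series).
#' @param calib a [conformal_calibrate()] result.
#' @param multipliers a [regime_multipliers()] vector.
#' @param labels regime labels aligned to `point` (from [label_regimes()]);
#'   defaults to all-`normal`.
#' @return an `interval_set`: data.frame with `point`, `lower`, `upper`,
#'   `regime`; attribute `level = 1 - alpha`.
#' @export
build_intervals <- function(point, calib, multipliers = regime_multipliers(),
                            labels = NULL) {
  n <- length(point)
  if (is.null(labels)) labels <- factor(rep("normal", n),
                                        levels = c("off_peak", "normal", "peak"))
  if (length(labels) != n) stop("labels not aligned to forecasts")
  if (anyNA(labels)) stop("missing regime label")
  w <- calib$q * unname(unclass(multipliers)[as.character(labels)])
  out <- data.frame(point = point, lower = point - w, upper = point + w,
                    regime = as.character(labels))
  attr(out, "level") <- 1 - calib$alpha
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Empirical coverage of prediction intervals
#'
#' Fraction of observations falling inside their interval, bounds
#' inclusive. With `by_regime = TRUE` also returns per-regime coverage
#' (relevant because the off-peak shrinkage is not guaranteed).
#'
#' @param intervals an `interval_set` from [build_intervals()].
#' @param y_true observed values aligned to the intervals.
#' @param by_regime also compute coverage within each regime.
#' @return coverage fraction, or a list `overall` / `by_regime`.
#' @export
empirical_coverage <- function(intervals, y_true, by_regime = FALSE) {
  if (nrow(intervals) != length(y_true)) stop("length mismatch")
  inside <- y_true >= intervals$lower & y_true <= intervals$upper
  if (!by_regime) return(mean(inside))
  list(overall = mean(inside),
       by_regime = tapply(inside, intervals$regime, mean))
}

#' Write an interval set as CSV
#'
#' One row per (date, feature): date, feature, point, lower, upper, regime
#' label and nominal level.
#'
#' @param intervals an `interval_set`.
#' @param dates dates aligned to rows.
#' @param feature feature name for this series.
#' @param path output path; appends without header if the file exists.
#' @return `path`, invisibly.
#' @export
write_intervals_csv <- function(intervals, dates, feature, path) {
  df <- data.frame(date = format(dates, "%Y-%m-%d"), feature = feature,
                   point = intervals$point, lower = intervals$lower,
                   upper = intervals$upper, regime = intervals$regime,
                   level = attr(intervals, "level"))
  first <- !file.exists(path)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = first, append = !first, quote = FALSE)
  invisible(path)
}
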