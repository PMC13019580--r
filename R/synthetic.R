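#' Specification of a synthetic daily count panel
#'
#' Describes the generative ground truth for an EHR-like panel: per-feature
#' baseline level and linear trend, sinusoidal seasonality at annual
#' (365.25 d), quarterly (90 d) and weekly (7 d) periods, an additive
#' calendar-quarter effect, abrupt changepoints with optional exponential
#' decay, and overdispersed count noise. Components compose additively on
#' the intensity scale (clipped at zero with a warning counter), so the
#' returned component truth is exact for recovery tests.
#'
#' @param n_days panel length in days.
#' @param start_date first calendar date.
#' @param features data.frame with columns `name`, `baseline` (mean daily
#'   count), `slope` (counts per year of linear trend), `amp_annual`,
#'   `amp_quarterly`, `amp_weekly` (sinusoid amplitudes, counts); optional
#'   `quad` and `cubic` columns (counts per year^2 / year^3) extend the
#'   trend to a low-order polynomial.
#' @param quarter_effect length-4 numeric: additive offset per calendar
#'   quarter as a fraction of baseline (Q1..Q4).
#' @param changepoints list of lists with `date`, `multiplier` (level
#'   shift of `(multiplier - 1) * baseline` at onset), `decay` (per-day
#'   exponential decay rate of the shift, 0 = permanent), and optional
#'   per-feature `weights` in \[0, 1\].
#' @param noise `"nbinom"` (negative binomial, `dispersion` = size
#'   parameter, variance `mu + mu^2/size`), `"poisson"`, or `"none"`
#'   (deterministic intensity).
#' @param dispersion negative-binomial size parameter.
#' @param annual_phase,weekly_phase phase offsets in days.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_days, start_date = as.Date("2017-01-02"),
                           features,
                           quarter_effect = c(0, 0, 0, 0),
                           changepoints = list(),
                           noise = c("nbinom", "poisson", "none"),
                           dispersion = 50,
                           annual_phase = -80, weekly_phase = 0) {
  noise <- match.arg(noise)
  stopifnot(n_days >= 1, nrow(features) >= 1,
            all(c("name", "baseline", "slope", "amp_annual", "amp_quarterly",
                  "amp_weekly") %in% names(features)),
            length(quarter_effect) == 4L, all(features$baseline >= 0),
            dispersion > 0)
  structure(list(n_days = as.integer(n_days), start_date = as.Date(start_date),
                 features = features, quarter_effect = quarter_effect,
                 changepoints = changepoints, noise = noise,
                 dispersion = dispersion, annual_phase = annual_phase,
                 weekly_phase = weekly_phase),
            class = "synthetic_spec")
}

#' Default 21-feature pediatric-style panel specification
#'
#' A stated-world stand-in for an undeposited six-year hospital panel:
#' 2,555 consecutive days and 21 indicators (two sexes, ages 2-14, six
#' disease systems). Baselines give roughly 109 total visits/day with a
#' 57/43 sex split; ages 2-6 carry higher baselines than ages 7-14;
#' respiratory disease dominates the system categories. Seasonality
#' combines annual, quarterly and weekly sinusoids with an additive
#' quarter effect making Q2-Q4 higher than Q1. A respiratory-surge
#' changepoint doubles the affected features' level in early 2022 and
#' decays at 1/300 per day, i.e. about 26% decline per quarter through
#' the final year. Noise is negative binomial (size 50, mildly
#' overdispersed).
#'
#' @return a `synthetic_spec`.
#' @export
default_pediatric_spec <- function() {
  nm <- c("Male", "Female", paste(2:14, "years old"),
          "Respiratory system diseases", "Neuromuscular system diseases",
          "Digestive system diseases", "Endocrine system diseases",
          "Urinary system diseases", "Mental and psychological disorders")
  baseline <- c(62, 47,                       # sexes
                12, 11, 10, 9, 8,             # ages 2-6 (higher)
                5, 4.5, 4, 3.8, 3.5, 3.2, 3, 2.8,  # ages 7-14
                55, 10, 25, 6, 5, 4)          # disease systems
  features <- data.frame(
    name = nm,
    baseline = baseline,
    slope = 0.06 * baseline,          # mild growth, counts per year
    amp_annual = 0.25 * baseline,
    amp_quarterly = 0.08 * baseline,
    amp_weekly = 0.10 * baseline)
  # respiratory surge hits respiratory + young ages + both sexes hardest
  w <- c(0.8, 0.8,                    # sexes
         0.9, 0.9, 0.9, 0.8, 0.8,    # ages 2-6
         rep(0.4, 8),                 # ages 7-14
         1.0, 0.2, 0.3, 0.1, 0.1, 0.1)
  synthetic_spec(
    n_days = 2555L,
    start_date = as.Date("2017-01-02"),
    features = features,
    quarter_effect = c(-0.08, 0.03, 0.05, 0.04),
    changepoints = list(list(date = as.Date("2022-01-15"), multiplier = 2.0,
                             decay = 1 / 300, weights = w)),
    noise = "nbinom", dispersion = 50)
}

#' Generate a synthetic panel with its component truth
#'
#' Draws counts from the configured noise family around the deterministic
#' intensity. Fully reproducible from `seed`. Negative composed
#' intensities are clipped to zero; the number of clipped cells is
#' attached as attribute `n_clipped` (with a warning when positive).
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer RNG seed.
#' @return list with `panel` (a `panel_series` of counts) and `truth`
#'   (a `components_truth`: per-feature `trend`, `seasonal`,
#'   `changepoint`, `intensity` matrices, all T x F, with
#'   `intensity == pmax(trend + seasonal + changepoint, 0)`).
#' @export
generate_panel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  T_ <- spec$n_days
  F_ <- nrow(spec$features)
  dates <- spec$start_date + seq_len(T_) - 1L
  t_days <- seq_len(T_) - 1
  qtr <- (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L
  trend <- matrix(0, T_, F_); seasonal <- matrix(0, T_, F_)
  cp <- matrix(0, T_, F_)
  for (j in seq_len(F_)) {
    f <- spec$features[j, ]
    ty <- t_days / 365.25
    quad <- if ("quad" %in% names(spec$features)) f$quad else 0
    cubic <- if ("cubic" %in% names(spec$features)) f$cubic else 0
    trend[, j] <- f$baseline + f$slope * ty + quad * ty^2 + cubic * ty^3
    seasonal[, j] <-
      f$amp_annual * sin(2 * pi * (t_days + spec$annual_phase) / 365.25) +
      f$amp_quarterly * sin(2 * pi * t_days / 90) +
      f$amp_weekly * sin(2 * pi * (t_days + spec$weekly_phase) / 7) +
      spec$quarter_effect[qtr] * f$baseline
  }
  for (c_ in spec$changepoints) {
    onset <- as.numeric(as.Date(c_$date) - spec$start_date)
    act <- t_days >= onset
    if (!any(act)) next
    w <- if (is.null(c_$weights)) rep(1, F_) else c_$weights
    shape <- exp(-c_$decay * (t_days[act] - onset))
    for (j in seq_len(F_)) {
      cp[act, j] <- cp[act, j] +
        (c_$multiplier - 1) * spec$features$baseline[j] * w[j] * shape
    }
  }
  intensity_raw <- trend + seasonal + cp
  n_clipped <- sum(intensity_raw < 0)
  if (n_clipped > 0) {
    warning(n_clipped, " negative intensity cells clipped to 0")
  }
  intensity <- pmax(intensity_raw, 0)
  nm <- spec$features$name
  colnames(trend) <- nm; colnames(seasonal) <- nm
  colnames(cp) <- nm; colnames(intensity) <- nm
  counts <- switch(spec$noise,
    none = intensity,
    poisson = matrix(stats::rpois(T_ * F_, intensity), T_, F_),
    nbinom = matrix(stats::rnbinom(T_ * F_, mu = intensity,
                                   size = spec$dispersion), T_, F_))
  panel <- panel_series(dates, counts, spec$features$name)
  truth <- structure(list(dates = dates, trend = trend, seasonal = seasonal,
                          changepoint = cp, intensity = intensity,
                          feature_names = spec$features$name),
                     class = "components_truth")
  attr(truth, "n_clipped") <- n_clipped
  list(panel = panel, truth = truth)
}
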