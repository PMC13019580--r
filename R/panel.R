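#' Daily multivariate count panel
#'
#' A `panel_series` is the universal data object of the package: a
#' date-indexed T x F matrix of daily patient counts (or normalized
#' incidence after scaling). Dates must be strictly increasing at exactly
#' one-day spacing, values must be finite, and the number of columns must
#' match the feature names.
#'
#' @param dates a `Date` vector, strictly increasing, daily spacing.
#' @param values numeric matrix with `length(dates)` rows.
#' @param feature_names character vector of column labels; defaults to the
#'   column names of `values`.
#' @return an object of class `panel_series` with fields `dates`, `values`
#'   (a named matrix) and `feature_names`.
#' @export
panel_series <- function(dates, values, feature_names = colnames(values)) {
  dates <- as.Date(dates)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    feature_names <- paste0("V", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length (", length(feature_names),
         ") does not match number of value columns (", ncol(values), ")")
  }
  if (length(dates) != nrow(values)) {
    stop("dates length does not match number of value rows")
  }
  if (anyNA(dates)) stop("dates contain NA")
  .check_daily(dates)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row ", bad[1L], ", column ", bad[2L])
  }
  colnames(values) <- feature_names
  structure(list(dates = dates, values = values,
                 feature_names = as.character(feature_names)),
            class = "panel_series")
}

# strict gap check: names the first offending (missing or duplicated) date
.check_daily <- function(dates) {
  if (length(dates) < 2L) return(invisible(TRUE))
  d <- diff(as.integer(dates))
  if (any(d <= 0L)) {
    i <- which(d <= 0L)[1L]
    stop("dates not strictly increasing at ", format(dates[i + 1L]),
         " (after ", format(dates[i]), ")")
  }
  if (any(d > 1L)) {
    i <- which(d > 1L)[1L]
    stop("calendar gap: missing date ", format(dates[i] + 1L),
         " (jump from ", format(dates[i]), " to ", format(dates[i + 1L]), ")")
  }
  invisible(TRUE)
}

#' @export
print.panel_series <- function(x, ...) {
  cat("<panel_series> ", nrow(x$values), " days x ", ncol(x$values),
      " features (", format(x$dates[1L]), " .. ",
      format(x$dates[length(x$dates)]), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.panel_series <- function(x) dim(x$values)

#' Number of days in a panel
#' @param panel a `panel_series`.
#' @return integer number of rows (days).
#' @export
n_days <- function(panel) nrow(panel$values)

#' Subset a panel by row indices (keeps dates aligned)
#' @param panel a `panel_series`.
#' @param idx integer row indices (must be contiguous and increasing).
#' @return a `panel_series` restricted to `idx`.
#' @export
panel_slice <- function(panel, idx) {
  idx <- as.integer(idx)
  panel_series(panel$dates[idx], panel$values[idx, , drop = FALSE],
               panel$feature_names)
}

#' Read a daily panel from CSV
#'
#' The expected dialect is a header row with a date column named `date`
#' (case-insensitive; the first column is used positionally otherwise)
#' followed by numeric count columns, ISO-8601 dates, UTF-8. Missing,
#' duplicated or non-consecutive dates are an error naming the offending
#' date; a non-numeric cell is an error naming its row and column.
#'
#' @param path path to a CSV file.
#' @return a `panel_series`.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("panel CSV needs a date column plus >= 1 numeric column")
  date_col <- which(tolower(names(raw)) == "date")
  date_col <- if (length(date_col)) date_col[1L] else 1L
  dates <- as.Date(raw[[date_col]], format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date at data row ", which(is.na(dates))[1L],
         ": '", raw[[date_col]][which(is.na(dates))[1L]], "'")
  }
  num <- raw[, -date_col, drop = FALSE]
  values <- matrix(NA_real_, nrow(num), ncol(num),
                   dimnames = list(NULL, names(num)))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric cell at data row ", i, ", column '", names(num)[j],
           "': '", num[[j]][i], "'")
    }
    values[, j] <- v
  }
  panel_series(dates, values, names(num))
}

#' Write a daily panel to CSV (same dialect as [read_panel_csv()])
#' @param panel a `panel_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  df <- data.frame(date = format(panel$dates, "%Y-%m-%d"),
                   panel$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit a per-feature min-max scaler on a (training) panel
#'
#' Per-feature minimum and maximum computed on the supplied slice only, so
#' that later slices can be mapped with training-set statistics. A constant
#' feature (max == min) is transformed to 0.
#'
#' @param panel a `panel_series` with at least 2 rows.
#' @return a `minmax_scaler` with fields `min`, `max`, `feature_names`,
#'   `method`.
#' @export
fit_scaler <- function(panel) {
  if (nrow(panel$values) < 2L) stop("need at least 2 rows to fit a scaler")
  structure(list(min = apply(panel$values, 2L, min),
                 max = apply(panel$values, 2L, max),
                 feature_names = panel$feature_names,
                 method = "minmax"),
            class = "minmax_scaler")
}

.check_scaler_match <- function(panel, scaler) {
  if (!identical(panel$feature_names, scaler$feature_names)) {
    stop("scaler feature names do not match panel feature names")
  }
}

#' Apply / invert min-max scaling
#'
#' `transform_panel` maps each feature affinely so the training minimum goes
#' to 0 and the training maximum to 1; values outside the training range map
#' outside \[0, 1\] (no clipping). `inverse_transform_panel` is its exact
#' inverse (round trip identical to within 1e-9).
#'
#' @param panel a `panel_series`.
#' @param scaler a `minmax_scaler` from [fit_scaler()] with matching features.
#' @return a `panel_series` on the transformed scale.
#' @export
transform_panel <- function(panel, scaler) {
  .check_scaler_match(panel, scaler)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1  # constant feature -> 0 after centering
  v <- sweep(sweep(panel$values, 2L, scaler$min, "-"), 2L, rng, "/")
  panel_series(panel$dates, v, panel$feature_names)
}

#' @rdname transform_panel
#' @export
inverse_transform_panel <- function(panel, scaler) {
  .check_scaler_match(panel, scaler)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1
  v <- sweep(sweep(panel$values, 2L, rng, "*"), 2L, scaler$min, "+")
  panel_series(panel$dates, v, panel$feature_names)
}

#' Chronological train / validation / test split
#'
#' The first `head_span` days form the in-sample period: the first
#' `floor(train_frac * head_span)` of them are the training slice and the
#' remainder the validation slice. Everything after `head_span` is the test
#' slice. The three slices are disjoint, ordered, and concatenate back to
#' the input panel.
#'
#' @param panel a `panel_series`.
#' @param head_span number of leading days forming train + validation
#'   (e.g. the first five years of a six-year panel).
#' @param train_frac fraction of `head_span` used for training, in (0, 1).
#' @return list with `panel_series` elements `train`, `val`, `test`.
#' @export
chronological_split <- function(panel, head_span, train_frac = 0.8) {
  T_ <- nrow(panel$values)
  if (head_span >= T_) stop("head_span (", head_span, ") must be < panel length (", T_, ")")
  if (!(train_frac > 0 && train_frac < 1)) stop("train_frac must be in (0, 1)")
  n_train <- floor(train_frac * head_span)
  if (n_train < 1L || n_train >= head_span) stop("degenerate split: train slice empty or full")
  list(train = panel_slice(panel, seq_len(n_train)),
       val   = panel_slice(panel, (n_train + 1L):head_span),
       test  = panel_slice(panel, (head_span + 1L):T_))
}

#' Sliding-window specification
#'
#' The basic time step is the forecast horizon `H`; the backcast (input)
#' length is `ratio * H`. Defaults follow the study design: horizon 30
#' days with a 7:1 past-to-future ratio, hence a 210-day input window.
#'
#' @param horizon forecast steps per window (H, default 30).
#' @param ratio integer past:future ratio (default 7).
#' @param stride origin spacing between consecutive windows (default 1).
#' @return a `window_spec` with fields `horizon`, `ratio`, `backcast`, `stride`.
#' @export
window_spec <- function(horizon = 30L, ratio = 7L, stride = 1L) {
  horizon <- as.integer(horizon); ratio <- as.integer(ratio); stride <- as.integer(stride)
  if (horizon < 1L || ratio < 1L || stride < 1L) stop("horizon, ratio and stride must be >= 1")
  structure(list(horizon = horizon, ratio = ratio,
                 backcast = ratio * horizon, stride = stride),
            class = "window_spec")
}

#' Build the sliding-window set of a panel
#'
#' Windows are 0-offset, half-open, contiguous: window with origin `s`
#' (1-based start index) has input rows `[s, s+L)` and target rows
#' `[s+L, s+L+H)`. At stride 1 there are `T - L - H + 1` windows.
#'
#' @param panel a `panel_series` of length at least `L + H`.
#' @param spec a [window_spec()].
#' @return a `window_set`: `inputs` (N x L x F array), `targets`
#'   (N x H x F), `origins` (1-based start index of each input window),
#'   `spec`, `feature_names`.
#' @export
make_windows <- function(panel, spec) {
  L <- spec$backcast; H <- spec$horizon
  T_ <- nrow(panel$values); F_ <- ncol(panel$values)
  if (T_ < L + H) {
    stop("series shorter than one window: need ", L + H, " days, have ", T_)
  }
  origins <- seq.int(1L, T_ - L - H + 1L, by = spec$stride)
  N <- length(origins)
  inputs <- array(0, c(N, L, F_))
  targets <- array(0, c(N, H, F_))
  for (k in seq_len(N)) {
    s <- origins[k]
    inputs[k, , ] <- panel$values[s:(s + L - 1L), ]
    targets[k, , ] <- panel$values[(s + L):(s + L + H - 1L), ]
  }
  structure(list(inputs = inputs, targets = targets, origins = origins,
                 spec = spec, feature_names = panel$feature_names),
            class = "window_set")
}
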